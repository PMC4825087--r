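# Bayesian variance-component estimation: chain management around the
# compiled Gibbs core, posterior summaries (means + HPD intervals, derived
# genetic parameters) and the Geweke convergence diagnostic.

#' Chain configuration for the Gibbs sampler
#'
#' Defaults follow the study protocol scaled to desk size: tests use
#' 20,000 iterations with 2,000 burn-in and thinning 10. The full-size
#' protocol is 250,000/25,000 (PED, GEN_UNI) and 500,000/50,000 (GEN),
#' thinning 10.
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations (`< iterations`).
#' @param thin save interval (`>= 1`).
#' @param seed integer seed.
#' @param convention flat-prior degrees-of-freedom convention. The default
#'   `"flat"` corresponds to a prior proportional to a constant on the
#'   variance scale: scalar conditionals are scaled inverse-chi-square with
#'   df = n - 2 and the 2x2 genetic block is inverse-Wishart with
#'   nu = n - 3. `"df_n"` uses df = n (nu = n), i.e. a Jeffreys-type
#'   prior |G0|^-(p+1)/2; note that this prior puts unbounded mass at
#'   singular G0 and the genetic-correlation chain can be absorbed at
#'   rg = +/-1 when the data are weak.
#' @return An object of class `tc_chain_config`.
#' @export
chain_config <- function(iterations = 20000, burn_in = 2000, thin = 10,
                         seed = 1, convention = c("flat", "df_n")) {
  convention <- match.arg(convention)
  if (burn_in >= iterations) stop_tc("burn_in must be < iterations")
  if (thin < 1) stop_tc("thin must be >= 1")
  if (floor((iterations - burn_in) / thin) < 1) {
    stop_tc("no saved draws: increase iterations or decrease thin")
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), convention = convention),
            class = "tc_chain_config")
}

.csc_list <- function(m) {
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  list(p = m@p, i = m@i, x = m@x, nrow = nrow(m))
}

#' Run a Gibbs chain for the variance components
#'
#' Location effects are re-sampled every iteration from their single-site
#' normal conditionals given the current mixed-model equations (the
#' equations are built once; only variance-dependent weights change).
#' Under flat priors the 2x2 sire-line genetic block is drawn from an
#' inverse-Wishart with scale `U' K_A^-1 U` and the scalar variances from
#' scaled inverse-chi-square conditionals. `K_A` is `A_A` for PED and `H`
#' for GEN (pass the corresponding inverse when assembling the MME).
#'
#' @param mme a [assemble_mme()] result.
#' @param config a [chain_config()].
#' @param start starting variance components (default: those in `mme`;
#'   the genetic block must be positive definite).
#' @param sample named list of logicals switching individual conditionals
#'   on/off (`location`, `genetic`, `bc`, `pen_a`, `pen_c`, `resid_a`,
#'   `resid_c`); all `TRUE` by default. Used by calibration tests.
#' @param theta_start optional start vector for the location effects.
#' @return An object of class `tc_chain`: `draws` (data.frame of saved
#'   variance draws + iteration stamps), `config`, `kind`, `counts`,
#'   `theta_mean` (posterior-mean location effects) and `layout`.
#' @export
run_chain <- function(mme, config, start = mme$vc, sample = list(),
                      theta_start = NULL) {
  stopifnot(inherits(mme, "tc_mme"), inherits(config, "tc_chain_config"))
  kind <- mme$kind
  mode <- switch(kind, PED = 0L, GEN = 0L, GEN_UNI_PB = 1L, GEN_UNI_CB = 2L)
  sflag <- function(nm) isTRUE(sample[[nm]] %||% TRUE)
  dfo <- if (config$convention == "df_n") c(scalar = 0L, wishart = 0L) else
           c(scalar = 2L, wishart = 3L)
  idx <- mme$design$idx
  empty_csc <- list(p = integer(1), i = integer(0), x = numeric(0), nrow = 0L)
  cfg <- list(iterations = config$iterations, burn_in = config$burn_in,
              thin = config$thin, mode = mode,
              dfoff_scalar = dfo[["scalar"]], dfoff_wishart = dfo[["wishart"]],
              sample_location = sflag("location"),
              sample_genetic = sflag("genetic"),
              sample_bc = sflag("bc"),
              sample_pen_a = sflag("pen_a"), sample_pen_c = sflag("pen_c"),
              sample_resid_a = sflag("resid_a"),
              sample_resid_c = sflag("resid_c"),
              start = unlist(start[c("s2A", "sAAC", "s2AC", "s2BC",
                                     "s2pA", "s2pC", "s2eA", "s2eC")]),
              theta_start = theta_start)
  KA <- if (is.null(mme$kin$A)) list() else .csc_list(mme$kin$A)[1:3]
  KB <- if (is.null(mme$kin$B)) list() else .csc_list(mme$kin$B)[1:3]
  MA <- if (nrow(mme$design$M_A)) .csc_list(mme$design$M_A) else empty_csc
  MC <- if (nrow(mme$design$M_C)) .csc_list(mme$design$M_C) else empty_csc

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  out <- .gibbs_core(mme$pattern$n, mme$pattern$p, mme$pattern$i, mme$V,
                     .ROLE_CODES[mme$roles], mme$rA, mme$rC,
                     MA, if (length(mme$design$y_A)) mme$design$y_A else numeric(0),
                     MC, if (length(mme$design$y_C)) mme$design$y_C else numeric(0),
                     KA, idx$uAA, idx$uAC, KB, idx$uBC,
                     idx$penA, idx$penC, cfg)
  draws <- as.data.frame(out$draws)
  draws$iteration <- out$iteration
  structure(list(draws = draws, config = config, kind = kind,
                 counts = mme$counts, theta_mean = out$theta_mean,
                 layout = mme$design$layout,
                 has_pen_a = length(idx$penA) > 0,
                 has_pen_c = length(idx$penC) > 0),
            class = "tc_chain")
}

#' @export
print.tc_chain <- function(x, ...) {
  cat(sprintf("<tc_chain> %s: %d saved draws (of %d iterations, burn-in %d, thin %d)\n",
              x$kind, nrow(x$draws), x$config$iterations, x$config$burn_in,
              x$config$thin))
  invisible(x)
}

#' Shortest interval containing a given posterior mass
#' @param x numeric draws.
#' @param mass interval mass (default 0.95).
#' @return Length-2 numeric `(low, high)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  j <- which.min(widths)
  c(x[j], x[j + m - 1L])
}

# derived genetic parameters, computed draw-by-draw
.derive_draws <- function(d, has_pen_a = TRUE, has_pen_c = TRUE) {
  pA <- if (has_pen_a) d$s2pA else 0
  pC <- if (has_pen_c) d$s2pC else 0
  s2phenA <- d$s2A + pA + d$s2eA
  s2C <- d$s2AC + d$s2BC + pC + d$s2eC
  data.frame(
    h2A = d$s2A / s2phenA,
    t2AC = 2 * d$s2AC / s2C,
    t2BC = 2 * d$s2BC / s2C,
    rg = d$sAAC / sqrt(d$s2A * d$s2AC),
    p2A = pA / s2phenA,
    p2C = pC / s2C,
    s2phenA = s2phenA,
    s2C = s2C)
}

#' Posterior summary of a chain
#'
#' Mean and shortest HPD interval per variance component, plus the derived
#' genetic parameters computed draw-by-draw and then summarized: purebred
#' heritability `h2A = s2A / (s2A + s2pA + s2eA)`, parental contribution
#' ratios `t2iC = 2 s2iC / s2C` with `s2C = s2AC + s2BC + s2pC + s2eC`
#' (the CB phenotypic variance; Mendelian-sampling variance lives inside
#' the residual), the genetic correlation `rg = sAAC / sqrt(s2A s2AC)`,
#' pen ratios and the phenotypic variances. All ratios are invariant to
#' gametic rescaling except the t2 definitions, which already carry the
#' factor 2.
#'
#' @param chain a [run_chain()] result (needs >= 100 saved draws).
#' @param hpd_mass HPD interval mass (default 0.95).
#' @return data.frame: parameter, mean, hpd_low, hpd_high.
#' @export
summarize_chain <- function(chain, hpd_mass = 0.95) {
  d <- chain$draws
  if (nrow(d) < 100) stop_tc("need >= 100 saved draws, have ", nrow(d))
  base <- d[, c("s2A", "sAAC", "s2AC", "s2BC", "s2pA", "s2pC",
                "s2eA", "s2eC")]
  der <- .derive_draws(d, chain$has_pen_a %||% TRUE, chain$has_pen_c %||% TRUE)
  all_ <- cbind(base, der)
  out <- lapply(names(all_), function(p) {
    x <- all_[[p]]
    h <- hpd_interval(x, hpd_mass)
    data.frame(parameter = p, mean = mean(x), hpd_low = h[1], hpd_high = h[2])
  })
  do.call(rbind, out)
}

# AR-based estimate of the spectral density at frequency zero
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-300) return(0)
  ord <- min(20L, max(1L, floor(length(x) / 5)))
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = ord),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first` fraction of the chain with the
#' mean of the last `last` fraction;
#' `z = (m1 - m2) / sqrt(se1^2 + se2^2)` with spectral-density variance
#' estimates at frequency zero (AR fit). A constant chain returns z = 0.
#'
#' @param chain a [run_chain()] result (needs >= 200 saved draws) or a
#'   data.frame/matrix of draws.
#' @param first,last fractions of the chain compared (defaults 0.1, 0.5).
#' @return Named numeric vector of z scores, one per parameter.
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  d <- if (inherits(chain, "tc_chain")) chain$draws else as.data.frame(chain)
  d$iteration <- NULL
  n <- nrow(d)
  if (n < 200) stop_tc("need >= 200 saved draws, have ", n)
  i1 <- seq_len(max(2L, floor(first * n)))
  i2 <- seq.int(n - max(2L, floor(last * n)) + 1L, n)
  vapply(names(d), function(p) {
    x1 <- d[[p]][i1]; x2 <- d[[p]][i2]
    v1 <- .spectrum0(x1) / length(x1)
    v2 <- .spectrum0(x2) / length(x2)
    if (v1 + v2 < 1e-300) return(0)
    (mean(x1) - mean(x2)) / sqrt(v1 + v2)
  }, numeric(1))
}

#' Posterior-mean variance components from a chain
#' @param chain a [run_chain()] result.
#' @return A [tc_vc()] built from the posterior means.
#' @export
posterior_vc <- function(chain) {
  m <- colMeans(chain$draws[, c("s2A", "sAAC", "s2AC", "s2BC",
                                "s2pA", "s2pC", "s2eA", "s2eC")])
  tc_vc(m[["s2A"]], m[["sAAC"]], m[["s2AC"]], m[["s2BC"]],
        m[["s2pA"]], m[["s2pC"]], m[["s2eA"]], m[["s2eC"]])
}

#' Write chain draws / posterior summary as TSV
#' @param chain a [run_chain()] result.
#' @param path output path.
#' @export
write_chain <- function(chain, path) {
  utils::write.table(chain$draws, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
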