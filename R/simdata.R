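# Synthetic terminal-cross data with known truth: two breed pedigrees,
# gene-dropped SNP genotypes for the sire line, correlated PB/CB genetic
# effects and station-style systematic effects.

#' Simulation configuration
#'
#' The `"study"` preset mirrors the scale of the motivating design: 90
#' genotyped sires, 306 crossbred dams, 654 purebred and 716 crossbred
#' half-sib offspring; the `"test"` preset is the reduced desk-scale
#' design (20 sires, 150 + 150 offspring, 1,000 SNPs). True variance
#' components default to h2_A = 0.30, t2_AC = t2_BC = 0.25, rg = 0.85
#' with unit phenotypic variances and pen ratios of about 0.10.
#'
#' @param preset `"test"` or `"study"`.
#' @param ... overrides of individual fields: `n_sires`, `n_dams_A`,
#'   `n_dams_B`, `pb_offspring`, `cb_offspring`, `n_snps`, `maf_range`,
#'   `n_batches`, `pens_per_batch`, `vc` (a [tc_vc()] of true components
#'   on the model scale: the CB residual includes the Mendelian-sampling
#'   variances), `mu_A`, `mu_C`, `batch_sd`, `cov_slope`, `cov_mean`,
#'   `cov_sd`, `genetic_model` (`"marker"` or `"polygenic"`).
#' @return An object of class `tc_sim_config`.
#' @export
sim_config <- function(preset = c("test", "study"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "test") {
    list(n_sires = 20L, n_dams_A = 70L, n_dams_B = 70L,
         pb_offspring = 150L, cb_offspring = 150L, n_snps = 1000L,
         n_batches = 4L, pens_per_batch = 5L)
  } else {
    list(n_sires = 90L, n_dams_A = 300L, n_dams_B = 306L,
         pb_offspring = 654L, cb_offspring = 716L, n_snps = 5000L,
         n_batches = 11L, pens_per_batch = 12L)
  }
  cfg$maf_range <- c(0.05, 0.5)
  # model-scale truth: s2C = s2AC + s2BC + s2pC + s2eC = 1,
  # t2AC = 2*s2AC/s2C = 0.25, h2A = 0.30, rg = 0.85
  cfg$vc <- tc_vc(s2A = 0.30, sAAC = 0.85 * sqrt(0.30 * 0.125),
                  s2AC = 0.125, s2BC = 0.125, s2pA = 0.10, s2pC = 0.09,
                  s2eA = 0.60, s2eC = 0.66)
  cfg$mu_A <- 10; cfg$mu_C <- 10.5
  cfg$batch_sd <- 0.5
  cfg$cov_slope <- 0.05; cfg$cov_mean <- 35; cfg$cov_sd <- 3
  cfg$genetic_model <- "marker"
  cfg$preset <- preset
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(cfg)))
  if (length(bad)) stop_tc("unknown sim_config field(s): ",
                           paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "tc_sim_config")
}

#' Simulate the terminal-cross mating design
#'
#' Sire-line base: grandparent pairs produce the sires; purebred dams are
#' base animals. Dam-line base: a set of dam-line sires produces the
#' crossbred dams. Every sire is mated to both purebred and crossbred
#' dams, so each sire has purebred and crossbred half-sib offspring;
#' offspring counts beyond the guaranteed one per sire are multinomial.
#' Dams are nested within sire.
#'
#' @param cfg a [sim_config()].
#' @return List: `ped_A`, `ped_B` (sorted pedigrees), `matings`
#'   (data.frame animal, sire, dam, type in PB/CB for the offspring).
#' @export
simulate_design <- function(cfg) {
  ns <- cfg$n_sires
  ngs <- max(1L, ceiling(ns * 0.75))
  gs <- sprintf("A_GS%03d", seq_len(ngs))
  gd <- sprintf("A_GD%03d", seq_len(ngs))
  sires <- sprintf("A_S%03d", seq_len(ns))
  sire_gs <- gs[(seq_len(ns) - 1L) %% ngs + 1L]
  sire_gd <- gd[(seq_len(ns) - 1L) %% ngs + 1L]
  damsA <- sprintf("A_D%03d", seq_len(cfg$n_dams_A))
  pb <- sprintf("A_O%04d", seq_len(cfg$pb_offspring))
  # dam line: founder sires + crossbred dams
  nbs <- max(1L, ceiling(cfg$n_dams_B / 5))
  bsires <- sprintf("B_S%03d", seq_len(nbs))
  damsB <- sprintf("B_D%03d", seq_len(cfg$n_dams_B))
  damB_sire <- bsires[(seq_len(cfg$n_dams_B) - 1L) %% nbs + 1L]
  cb <- sprintf("X_O%04d", seq_len(cfg$cb_offspring))

  # offspring counts per sire: 1 guaranteed + multinomial remainder
  alloc <- function(total) {
    base <- rep(1L, ns)
    extra <- total - ns
    if (extra < 0) stop_tc("fewer offspring than sires")
    if (extra > 0) {
      base + as.integer(stats::rmultinom(1, extra, rep(1 / ns, ns)))
    } else base
  }
  pb_cnt <- alloc(cfg$pb_offspring)
  cb_cnt <- alloc(cfg$cb_offspring)
  pb_sire <- rep(sires, pb_cnt)
  cb_sire <- rep(sires, cb_cnt)
  # dams nested within sire: split the dam list proportionally to offspring
  assign_dams <- function(offs_sire, dams) {
    sire_of_dam <- rep(sires, length.out = length(dams))
    out <- character(length(offs_sire))
    for (s in sires) {
      k <- which(offs_sire == s)
      pool <- dams[sire_of_dam == s]
      if (!length(pool)) pool <- dams
      out[k] <- pool[(seq_along(k) - 1L) %% length(pool) + 1L]
    }
    out
  }
  pb_dam <- assign_dams(pb_sire, damsA)
  cb_dam <- assign_dams(cb_sire, damsB)

  ped_A <- tc_pedigree(
    id   = c(gs, gd, damsA, sires, pb),
    sire = c(rep(NA, 2 * ngs), rep(NA, length(damsA)), sire_gs, pb_sire),
    dam  = c(rep(NA, 2 * ngs), rep(NA, length(damsA)), sire_gd, pb_dam),
    line = "sire_line")
  attr(ped_A, "sorted") <- TRUE
  ped_B <- tc_pedigree(
    id   = c(bsires, damsB),
    sire = c(rep(NA, nbs), damB_sire),
    dam  = c(rep(NA, nbs), rep(NA, length(damsB))),
    line = "dam_line")
  attr(ped_B, "sorted") <- TRUE
  matings <- data.frame(
    animal = c(pb, cb),
    sire = c(pb_sire, cb_sire),
    dam = c(pb_dam, cb_dam),
    type = rep(c("PB", "CB"), c(length(pb), length(cb))),
    stringsAsFactors = FALSE)
  list(ped_A = ped_A, ped_B = ped_B, matings = matings,
       sires = sires, founders_A = c(gs, gd, damsA))
}

#' Gene-drop SNP genotypes down the sire-line pedigree
#'
#' Base-animal alleles are Bernoulli draws with per-locus frequencies
#' `q_j ~ Uniform(maf_range)` for the 0-coded allele; descendants inherit
#' one allele per parent per locus, independently across loci (no linkage
#' map). The genotyped set is the sires plus the purebred offspring.
#'
#' @param cfg a [sim_config()].
#' @param ped_A sorted sire-line pedigree.
#' @return List: `panel` (full-pedigree [tc_panel()]), `genotyped` (ids),
#'   `q` (true base frequencies of the 0-coded allele).
#' @export
simulate_genotypes <- function(cfg, ped_A) {
  .assert_sorted(ped_A)
  pc <- .ped_codes(ped_A)
  n <- pc$n; p <- cfg$n_snps
  q <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
  # haplotypes carry the NON-0-coded allele as 1, so code = h1 + h2
  h1 <- matrix(0L, n, p)
  h2 <- matrix(0L, n, p)
  draw_base <- function() {
    matrix(rbinom(n = p, size = 1, prob = 1 - q), nrow = 1)
  }
  for (i in seq_len(n)) {
    s <- pc$s[i]; d <- pc$d[i]
    h1[i, ] <- if (s == 0L) rbinom(p, 1, 1 - q) else {
      pick <- runif(p) < 0.5
      ifelse(pick, h1[s, ], h2[s, ])
    }
    h2[i, ] <- if (d == 0L) rbinom(p, 1, 1 - q) else {
      pick <- runif(p) < 0.5
      ifelse(pick, h1[d, ], h2[d, ])
    }
  }
  codes <- h1 + h2
  rownames(codes) <- ped_A$id
  colnames(codes) <- sprintf("snp%05d", seq_len(p))
  genotyped <- ped_A$id[grepl("^A_S|^A_O", ped_A$id)]
  list(panel = tc_panel(codes), genotyped = genotyped, q = q)
}

# symmetric matrix square root via eigendecomposition (PSD-safe)
.msqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate true genetic effects
#'
#' Sire-line `(u_AA, u_AC)` pairs come from shared per-SNP effects: each
#' locus gets a bivariate-normal effect pair with covariance proportional
#' to the true genetic block G0, so the genomic data are genuinely
#' informative (switch `genetic_model = "polygenic"` for a pedigree-only
#' truth). Dam-line `u_BC` is polygenic via pedigree recursion. Empirical
#' (co)variances over the sire-line base animals are rescaled to hit the
#' configured targets exactly.
#'
#' @param cfg a [sim_config()].
#' @param design a [simulate_design()] result.
#' @param geno a [simulate_genotypes()] result (marker model).
#' @return List: `u_AA`, `u_AC` (named over ped_A), `u_BC` (named over
#'   ped_B), `vc` (the true [tc_vc()]), `snp_effects`.
#' @export
simulate_effects <- function(cfg, design, geno = NULL) {
  vc <- cfg$vc
  G0 <- matrix(c(vc$s2A, vc$sAAC, vc$sAAC, vc$s2AC), 2)
  ped_A <- design$ped_A
  nA <- nrow(ped_A)
  base_ids <- design$founders_A
  snp_eff <- NULL

  if (cfg$genetic_model == "marker") {
    if (is.null(geno)) stop_tc("marker genetic model needs genotypes")
    X <- geno$panel$codes
    p <- ncol(X)
    # per-SNP bivariate effects, covariance proportional to G0
    Z <- matrix(rnorm(2 * p), p, 2)
    snp_eff <- Z %*% chol(G0 / p + diag(1e-12, 2))
    U <- X %*% snp_eff
  } else {
    # polygenic gene flow under A_A with base variance G0
    U <- matrix(0, nA, 2)
    pc <- .ped_codes(ped_A)
    L <- chol(G0)
    for (i in seq_len(nA)) {
      s <- pc$s[i]; d <- pc$d[i]
      par <- (if (s > 0L) U[s, ] else c(0, 0)) / 2 +
             (if (d > 0L) U[d, ] else c(0, 0)) / 2
      msv <- 1 - 0.25 * ((s > 0L) + (d > 0L))  # base Mendelian variance
      U[i, ] <- par + sqrt(msv) * as.numeric(rnorm(2) %*% L)
    }
  }
  rownames(U) <- ped_A$id
  # rescale so the empirical base covariance equals G0 exactly
  B <- U[base_ids, , drop = FALSE]
  B <- sweep(B, 2, colMeans(B))
  Cemp <- crossprod(B) / (nrow(B) - 1)
  Tm <- solve(.msqrt(Cemp + diag(1e-12, 2))) %*% .msqrt(G0)
  U <- sweep(U, 2, colMeans(U[base_ids, , drop = FALSE])) %*% Tm

  # dam line: polygenic recursion, scalar rescale over its base animals
  ped_B <- design$ped_B
  pcB <- .ped_codes(ped_B)
  nB <- nrow(ped_B)
  uBC <- numeric(nB)
  for (i in seq_len(nB)) {
    s <- pcB$s[i]; d <- pcB$d[i]
    par <- (if (s > 0L) uBC[s] else 0) / 2 + (if (d > 0L) uBC[d] else 0) / 2
    msv <- 1 - 0.25 * ((s > 0L) + (d > 0L))
    uBC[i] <- par + sqrt(msv) * rnorm(1)
  }
  baseB <- which(pcB$s == 0L & pcB$d == 0L)
  sdB <- stats::sd(uBC[baseB])
  if (sdB > 0) uBC <- uBC * sqrt(vc$s2BC) / sdB
  names(uBC) <- ped_B$id

  list(u_AA = setNames(U[, 1], ped_A$id),
       u_AC = setNames(U[, 2], ped_A$id),
       u_BC = uBC, vc = vc, snp_effects = snp_eff)
}

#' Simulate phenotypes under the terminal-cross model
#'
#' `y_PB = mu_A + batch + slope * covariate + pen + u_AA + e_A`;
#' `y_CB = mu_C + batch + slope * covariate + pen + u_AC(sire) +
#' u_BC(dam) + phi_A + phi_B + e_C`, with per-offspring Mendelian-sampling
#' terms `phi_A ~ N(0, s2AC)` and `phi_B ~ N(0, s2BC)` (these live in the
#' model's CB residual, so the generator draws the pure residual with
#' variance `s2eC - s2AC - s2BC`). Batches and pens are assigned
#' round-robin; pens are nested within batch and separate per breed type.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_effects()] result.
#' @param design a [simulate_design()] result.
#' @return A trait table (data.frame) with trait column `perf`.
#' @export
simulate_phenotypes <- function(cfg, truth, design) {
  vc <- cfg$vc
  m <- design$matings
  nrec <- nrow(m)
  batch <- sprintf("b%02d", (seq_len(nrec) - 1L) %% cfg$n_batches + 1L)
  pen_no <- (seq_len(nrec) - 1L) %/% cfg$n_batches %% cfg$pens_per_batch + 1L
  pen <- sprintf("%s:%s:p%02d", batch, tolower(m$type), pen_no)
  w <- rnorm(nrec, cfg$cov_mean, cfg$cov_sd)
  beff_A <- setNames(rnorm(cfg$n_batches, 0, cfg$batch_sd),
                     sprintf("b%02d", seq_len(cfg$n_batches)))
  beff_C <- setNames(rnorm(cfg$n_batches, 0, cfg$batch_sd),
                     sprintf("b%02d", seq_len(cfg$n_batches)))
  pens <- unique(pen)
  peff <- setNames(c(rnorm(sum(grepl(":pb:", pens)), 0, sqrt(vc$s2pA)),
                     rnorm(sum(grepl(":cb:", pens)), 0, sqrt(vc$s2pC))),
                   c(pens[grepl(":pb:", pens)], pens[grepl(":cb:", pens)]))
  is_pb <- m$type == "PB"
  y <- numeric(nrec)
  y[is_pb] <- cfg$mu_A + beff_A[batch[is_pb]] + cfg$cov_slope * w[is_pb] +
    peff[pen[is_pb]] + truth$u_AA[m$animal[is_pb]] +
    rnorm(sum(is_pb), 0, sqrt(vc$s2eA))
  s2eC_pure <- vc$s2eC - vc$s2AC - vc$s2BC
  if (s2eC_pure < 0) stop_tc("s2eC must exceed s2AC + s2BC (it absorbs the ",
                             "Mendelian-sampling variances)")
  y[!is_pb] <- cfg$mu_C + beff_C[batch[!is_pb]] + cfg$cov_slope * w[!is_pb] +
    peff[pen[!is_pb]] + truth$u_AC[m$sire[!is_pb]] +
    truth$u_BC[m$dam[!is_pb]] +
    rnorm(sum(!is_pb), 0, sqrt(vc$s2AC)) +   # phi_A
    rnorm(sum(!is_pb), 0, sqrt(vc$s2BC)) +   # phi_B
    rnorm(sum(!is_pb), 0, sqrt(max(s2eC_pure, 0)))
  data.frame(animal = m$animal, breed_type = m$type, sire = m$sire,
             dam = m$dam, batch = batch, pen = pen, start_weight = w,
             perf = y, stringsAsFactors = FALSE)
}

#' Simulate a complete terminal-cross dataset
#'
#' Runs [simulate_design()], [simulate_genotypes()], [simulate_effects()]
#' and [simulate_phenotypes()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return An object of class `tc_simdata`: `ped_A`, `ped_B`, `panel`
#'   (genotyped animals only), `panel_full`, `genotyped`, `data` (trait
#'   table), `truth`, `sires`, `cfg`, `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config("test"), seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  design <- simulate_design(cfg)
  geno <- simulate_genotypes(cfg, design$ped_A)
  truth <- simulate_effects(cfg, design, geno)
  data <- simulate_phenotypes(cfg, truth, design)
  panel <- tc_panel(geno$panel$codes[geno$genotyped, , drop = FALSE])
  structure(list(ped_A = design$ped_A, ped_B = design$ped_B,
                 panel = panel, panel_full = geno$panel,
                 genotyped = geno$genotyped, data = data, truth = truth,
                 sires = design$sires, cfg = cfg, seed = seed),
            class = "tc_simdata")
}

#' @export
print.tc_simdata <- function(x, ...) {
  cat(sprintf(
    "<tc_simdata> seed %d: %d sire-line + %d dam-line animals, %d records, %d SNPs\n",
    x$seed, nrow(x$ped_A), nrow(x$ped_B), nrow(x$data), ncol(x$panel$codes)))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `pedigree_A.csv`, `pedigree_B.csv`, `phenotypes.tsv`,
#' `genotypes.tsv`, `truth.tsv` (animal, u_AA, u_AC, u_BC) and
#' `truth_vc.tsv` in the package's file formats.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$ped_A, file.path(dir, "pedigree_A.csv"))
  write_pedigree(sim$ped_B, file.path(dir, "pedigree_B.csv"))
  write_trait_table(sim$data, file.path(dir, "phenotypes.tsv"))
  write_genotypes(sim$panel, file.path(dir, "genotypes.tsv"))
  tr <- data.frame(animal = c(names(sim$truth$u_AA), names(sim$truth$u_BC)),
                   u_AA = c(sim$truth$u_AA, rep(NA, length(sim$truth$u_BC))),
                   u_AC = c(sim$truth$u_AC, rep(NA, length(sim$truth$u_BC))),
                   u_BC = c(rep(NA, length(sim$truth$u_AA)), sim$truth$u_BC))
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vc <- sim$truth$vc
  utils::write.table(data.frame(parameter = names(unlist(vc)),
                                value = unlist(vc)),
                     file.path(dir, "truth_vc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
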