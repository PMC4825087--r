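# Variance components, Henderson mixed-model equations, BLUP solving,
# prediction error variances and theoretical accuracies.

#' Variance components of the terminal-cross model
#'
#' All values on the gametic (fitted) scale: `s2AC` and `s2BC` are the
#' variances of the parental gametic contributions, one quarter of the
#' corresponding breeding-value variances. The 2x2 sire-line genetic block
#' `G0 = [[s2A, sAAC], [sAAC, s2AC]]` must be positive definite.
#'
#' @param s2A additive genetic variance, PB performance (sire line).
#' @param sAAC additive genetic covariance between `u_AA` and `u_AC`.
#' @param s2AC sire-line gametic variance for CB performance.
#' @param s2BC dam-line gametic variance for CB performance.
#' @param s2pA,s2pC pen variances (0 when the recipe has no pen effect).
#' @param s2eA,s2eC residual variances (the CB residual absorbs the
#'   Mendelian-sampling terms).
#' @return An object of class `tc_vc` with attribute `scale = "gametic"`.
#' @export
tc_vc <- function(s2A, sAAC, s2AC, s2BC, s2pA = 0, s2pC = 0, s2eA, s2eC) {
  v <- list(s2A = s2A, sAAC = sAAC, s2AC = s2AC, s2BC = s2BC,
            s2pA = s2pA, s2pC = s2pC, s2eA = s2eA, s2eC = s2eC)
  if (any(unlist(v[c("s2A", "s2AC", "s2BC", "s2eA", "s2eC")]) <= 0)) {
    stop_tc("variances s2A, s2AC, s2BC, s2eA, s2eC must be > 0")
  }
  if (s2A * s2AC - sAAC^2 <= 0) {
    stop_tc("genetic block G0 is not positive definite ",
            sprintf("(det = %.3g)", s2A * s2AC - sAAC^2))
  }
  structure(v, class = "tc_vc", scale = "gametic")
}

#' @export
print.tc_vc <- function(x, ...) {
  cat(sprintf("<tc_vc> [%s scale] ", attr(x, "scale")))
  cat(paste(names(x), signif(unlist(x), 4), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Genetic correlation between PB and CB performance implied by a tc_vc
#' @param vc a [tc_vc()].
#' @return `sAAC / sqrt(s2A * s2AC)`; invariant to gametic rescaling.
#' @export
rg_of <- function(vc) vc$sAAC / sqrt(vc$s2A * vc$s2AC)

#' Rescale gametic contributions to the breeding-value scale
#'
#' Each gametic contribution transmits half a breeding value, so solutions
#' are multiplied by 2, gametic variances by 4 and the PB/CB covariance by
#' 2; the genetic correlation is unchanged. Objects carry a scale tag and
#' a second application is rejected.
#'
#' @param x a [tc_vc()] or a numeric vector of gametic solutions with
#'   attribute `scale = "gametic"`.
#' @return The rescaled object, tagged `scale = "breeding_value"`.
#' @export
rescale_gametic <- function(x) UseMethod("rescale_gametic")

#' @export
rescale_gametic.tc_vc <- function(x) {
  if (identical(attr(x, "scale"), "breeding_value")) {
    stop_tc("already on the breeding-value scale; refusing to rescale twice")
  }
  y <- x
  y$s2AC <- 4 * x$s2AC
  y$s2BC <- 4 * x$s2BC
  y$sAAC <- 2 * x$sAAC
  attr(y, "scale") <- "breeding_value"
  y
}

#' @export
rescale_gametic.default <- function(x) {
  if (identical(attr(x, "scale"), "breeding_value")) {
    stop_tc("already on the breeding-value scale; refusing to rescale twice")
  }
  y <- 2 * x
  attributes(y) <- attributes(x)
  attr(y, "scale") <- "breeding_value"
  y
}

# Component roles understood by the Gibbs core (must match gibbs_core.cpp):
# eA eC  : data cross-products, weights 1/s2eA, 1/s2eC
# g11 g12 g22 : K_A^-1 embedded in the (uAA,uAC) blocks, weights = G0^-1
# gA gAC : K_A^-1 on uAA (resp. uAC) alone for the univariate kinds
# bc pA pC : K_B^-1 / s2BC and pen identities
.ROLE_CODES <- c(eA = 0L, eC = 1L, g11 = 2L, g12 = 3L, g22 = 4L,
                 bc = 5L, pA = 6L, pC = 7L, gA = 8L, gAC = 9L)

.role_weights <- function(roles, vc) {
  g0 <- matrix(c(vc$s2A, vc$sAAC, vc$sAAC, vc$s2AC), 2)
  g0i <- solve(g0)
  w <- c(eA = 1 / vc$s2eA, eC = 1 / vc$s2eC,
         g11 = g0i[1, 1], g12 = g0i[1, 2], g22 = g0i[2, 2],
         bc = 1 / vc$s2BC, pA = 1 / max(vc$s2pA, .Machine$double.xmin),
         pC = 1 / max(vc$s2pC, .Machine$double.xmin),
         gA = 1 / vc$s2A, gAC = 1 / vc$s2AC)
  unname(w[roles])
}

.embed <- function(K, rows, cols, n) {
  Kt <- methods::as(methods::as(K, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = rows[Kt@i + 1L], j = cols[Kt@j + 1L], x = Kt@x,
                       dims = c(n, n))
}

#' Assemble Henderson mixed-model equations
#'
#' Builds the coefficient matrix as a weighted sum of fixed sparse
#' components: data cross-products per breed type (heterogeneous residual
#' weights), the sire-line genetic block `G0^-1 (x) K_A^-1` over the
#' stacked `(u_AA, u_AC)` equations, the dam block `K_B^-1 / s2BC`, and
#' identity pen blocks. For the GEN kind, pass `H^-1` as `kinship$A`.
#'
#' @param design a [build_design()] result.
#' @param vc a [tc_vc()].
#' @param kinship list with `A` (sparse `A_A^-1` or `H^-1`, id order =
#'   `design$ids_A`) and, for CB kinds, `B` (sparse `A_B^-1`).
#' @return An object of class `tc_mme`.
#' @export
assemble_mme <- function(design, vc, kinship) {
  kind <- design$spec$kind
  n <- nrow(design$layout)
  idx <- design$idx
  KA <- kinship$A
  KB <- kinship$B
  if (length(idx$uAA) || length(idx$uAC)) {
    if (is.null(KA)) stop_tc("kinship$A required")
    if (!identical(rownames(KA), design$ids_A)) {
      stop_tc("kinship$A id order must match design$ids_A")
    }
  }
  if (length(idx$uBC)) {
    if (is.null(KB)) stop_tc("kinship$B required for CB kinds")
    if (!identical(rownames(KB), design$ids_B)) {
      stop_tc("kinship$B id order must match design$ids_B")
    }
  }

  comps <- list(); roles <- character(0)
  push <- function(m, role) {
    # expand symmetric storage to full general storage so that value
    # alignment covers both triangles
    comps[[length(comps) + 1L]] <<-
      methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    roles <<- c(roles, role)
  }
  if (nrow(design$M_A)) push(Matrix::crossprod(design$M_A), "eA")
  if (nrow(design$M_C)) push(Matrix::crossprod(design$M_C), "eC")
  if (.bivariate(kind)) {
    push(.embed(KA, idx$uAA, idx$uAA, n), "g11")
    push(.embed(KA, idx$uAA, idx$uAC, n) + .embed(KA, idx$uAC, idx$uAA, n),
         "g12")
    push(.embed(KA, idx$uAC, idx$uAC, n), "g22")
  } else if (kind == "GEN_UNI_PB") {
    push(.embed(KA, idx$uAA, idx$uAA, n), "gA")
  } else {
    push(.embed(KA, idx$uAC, idx$uAC, n), "gAC")
  }
  if (length(idx$uBC)) push(.embed(KB, idx$uBC, idx$uBC, n), "bc")
  if (length(idx$penA)) {
    push(Matrix::sparseMatrix(i = idx$penA, j = idx$penA,
                              x = rep(1, length(idx$penA)),
                              dims = c(n, n)), "pA")
  }
  if (length(idx$penC)) {
    push(Matrix::sparseMatrix(i = idx$penC, j = idx$penC,
                              x = rep(1, length(idx$penC)),
                              dims = c(n, n)), "pC")
  }

  # Union sparsity pattern; every equation has a diagonal entry.
  pat <- Reduce(`+`, lapply(comps, abs)) + Matrix::Diagonal(n, 1e-300)
  pat <- methods::as(methods::as(pat, "generalMatrix"), "CsparseMatrix")
  key_pat <- .csc_keys(pat, n)
  V <- matrix(0, length(pat@x), length(comps))
  for (k in seq_along(comps)) {
    ck <- comps[[k]]
    pos <- match(.csc_keys(ck, n), key_pat)
    stopifnot(!anyNA(pos))
    V[pos, k] <- ck@x
  }

  rA <- as.numeric(Matrix::crossprod(design$M_A, design$y_A))
  rC <- as.numeric(Matrix::crossprod(design$M_C, design$y_C))
  if (!length(rA)) rA <- numeric(n)
  if (!length(rC)) rC <- numeric(n)

  structure(list(
    pattern = list(p = pat@p, i = pat@i, n = n),
    V = V, roles = roles,
    rA = rA, rC = rC,
    design = design, vc = vc,
    kin = list(A = KA, B = KB),
    counts = list(nrecA = nrow(design$M_A), nrecC = nrow(design$M_C),
                  nA = length(design$ids_A), nB = length(design$ids_B),
                  npenA = length(idx$penA), npenC = length(idx$penC)),
    kind = kind
  ), class = "tc_mme")
}

.csc_keys <- function(m, n) {
  cols <- rep.int(seq_len(ncol(m)), diff(m@p))
  as.numeric(m@i) + as.numeric(n) * (cols - 1)
}

#' @export
print.tc_mme <- function(x, ...) {
  cat(sprintf("<tc_mme> %s: %d equations, %d nonzeros, %d components\n",
              x$kind, x$pattern$n, length(x$pattern$i), ncol(x$V)))
  invisible(x)
}

#' Coefficient matrix of the MME at given variance components
#' @param mme a [assemble_mme()] result.
#' @param vc variance components (default: those stored in `mme`).
#' @return Sparse symmetric Matrix.
#' @export
mme_matrix <- function(mme, vc = mme$vc) {
  w <- .role_weights(mme$roles, vc)
  x <- as.numeric(mme$V %*% w)
  n <- mme$pattern$n
  methods::new("dgCMatrix", p = mme$pattern$p, i = mme$pattern$i,
               x = x, Dim = c(n, n))
}

.mme_rhs <- function(mme, vc = mme$vc) {
  mme$rA / vc$s2eA + mme$rC / vc$s2eC
}

#' Solve the mixed-model equations (BLUP)
#'
#' Direct sparse symmetric factorization of the coefficient matrix. The
#' relative residual of the solved system must not exceed `1e-8`.
#'
#' @param mme a [assemble_mme()] result.
#' @param vc variance components (default: stored).
#' @return An object of class `tc_fit`: `solution` (named by
#'   `effect:level`), `layout`, `vc`, `spec`, plus the Cholesky factor for
#'   reuse.
#' @export
solve_blup <- function(mme, vc = mme$vc) {
  C <- mme_matrix(mme, vc)
  rhs <- .mme_rhs(mme, vc)
  Ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE, perm = TRUE),
    error = function(e) {
      nm <- .null_space_effect(C, mme$design$layout)
      stop_tc("MME coefficient matrix is not positive definite",
              if (!is.null(nm)) paste0(" (null space loads on ", nm, ")"))
    })
  sol <- as.numeric(Matrix::solve(Ch, rhs))
  res <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2))
  nr <- sqrt(sum(rhs^2))
  if (nr > 0 && res > 1e-8 * nr) {
    stop_tc(sprintf("MME solve did not converge: ||Cx-r|| = %.3g ||r||",
                    res / nr))
  }
  names(sol) <- paste(mme$design$layout$effect, mme$design$layout$level,
                      sep = ":")
  structure(list(solution = sol, layout = mme$design$layout, vc = vc,
                 spec = mme$design$spec, chol = Ch, mme = mme),
            class = "tc_fit")
}

.null_space_effect <- function(C, layout) {
  n <- nrow(C)
  if (n > 3000) return(NULL)
  ev <- eigen(as.matrix(Matrix::forceSymmetric(C)), symmetric = TRUE)
  v <- ev$vectors[, n]
  j <- which.max(abs(v))
  paste0(layout$effect[j], ":", layout$level[j])
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("<tc_fit> %s/%s: %d equations solved\n", x$spec$kind,
              x$spec$trait, length(x$solution)))
  invisible(x)
}

#' Extract solutions of one effect block from a fit
#' @param fit a [solve_blup()] result.
#' @param effect block name (`"uAA"`, `"uAC"`, `"uBC"`, `"fixedA"`, ...).
#' @return Named numeric vector over the block's levels.
#' @export
fit_effect <- function(fit, effect) {
  sel <- fit$layout$effect == effect
  setNames(fit$solution[fit$layout$index[sel]], fit$layout$level[sel])
}

#' Prediction error variances and theoretical accuracies of EBV
#'
#' PEV of an animal x performance is the corresponding diagonal entry of
#' the inverse (factorized) MME coefficient matrix; the accuracy is
#' `R = sqrt(1 - PEV / ((1 + F) * s2_k))` with `s2_k = s2A` for PB
#' performance and the gametic `s2AC` for CB performance (R is invariant
#' to the x2 rescaling because PEV and variance scale together).
#'
#' @param fit a [solve_blup()] result (factorization is reused).
#' @param targets data.frame with columns `animal` and `performance`
#'   (`"PB"` or `"CB"`).
#' @param F named inbreeding vector over sire-line animals
#'   (from [compute_inbreeding()]).
#' @param vc variance components (default: from the fit).
#' @param genotyped optional ids flagged genotyped in the report.
#' @param data optional trait table used to flag `own_record`.
#' @return EBV report data.frame: animal, performance, ebv, ebv_rescaled,
#'   pev, accuracy, f, genotyped, own_record.
#' @export
compute_accuracy <- function(fit, targets, F, vc = fit$vc,
                             genotyped = character(0), data = NULL) {
  layout <- fit$layout
  eqs <- integer(nrow(targets))
  s2k <- numeric(nrow(targets))
  for (r in seq_len(nrow(targets))) {
    perf <- targets$performance[r]
    block <- if (perf == "PB") "uAA" else "uAC"
    sel <- layout$effect == block
    j <- layout$index[sel][match(targets$animal[r], layout$level[sel])]
    if (is.na(j)) {
      stop_tc("target not in layout: ", targets$animal[r], " / ", perf)
    }
    eqs[r] <- j
    s2k[r] <- if (perf == "PB") vc$s2A else vc$s2AC
  }
  n <- length(fit$solution)
  E <- Matrix::sparseMatrix(i = eqs, j = seq_along(eqs),
                            x = rep(1, length(eqs)), dims = c(n, length(eqs)))
  S <- Matrix::solve(fit$chol, E)
  pev <- as.numeric(Matrix::colSums(E * S))
  Fv <- unname(F[targets$animal])
  Fv[is.na(Fv)] <- 0
  cap <- (1 + Fv) * s2k
  over <- pev > cap * (1 + 1e-6) + 1e-10
  if (any(over)) {
    bad <- which.max(pev / cap)
    msg <- sprintf(
      "PEV exceeds (1+F) s2_k for %s/%s (%.6g > %.6g)",
      targets$animal[bad], targets$performance[bad], pev[bad], cap[bad])
    if (fit$spec$kind == "PED") {
      # with pedigree kinship the prior variance is exactly (1+F) s2_k,
      # so this signals a variance-component/coefficient mismatch
      stop_tc(msg, ": variance components do not match the coefficient ",
              "matrix")
    }
    # under H the prior variance is s2_k * H_ii, and genomic diagonals can
    # exceed the pedigree 1+F; the R formula keeps pedigree F regardless,
    # so clamp the affected accuracies at 0 and warn
    warning(msg, " (genomic diagonal above the pedigree 1+F); ",
            "accuracy clamped at 0", call. = FALSE)
  }
  ebv <- fit$solution[eqs]
  resc <- ifelse(targets$performance == "CB", 2 * ebv, ebv)
  own <- if (is.null(data)) NA else {
    mapply(function(a, p) {
      any(data$animal == a &
            data$breed_type == ifelse(p == "PB", "PB", "CB"))
    }, targets$animal, targets$performance)
  }
  data.frame(
    animal = targets$animal,
    performance = targets$performance,
    ebv = unname(ebv),
    ebv_rescaled = unname(resc),
    pev = pev,
    accuracy = sqrt(pmax(0, 1 - pev / cap)),
    f = Fv,
    genotyped = targets$animal %in% genotyped,
    own_record = unname(own),
    stringsAsFactors = FALSE)
}
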