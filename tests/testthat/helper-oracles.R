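# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written along different algorithmic paths than
# the implementation (recursive kinship instead of the tabular loop, dense
# GLS instead of the sparse mixed-model equations).

# --- random pedigree generator -----------------------------------------

random_pedigree <- function(n, seed, p_founder = 0.3) {
  set.seed(seed)
  id <- sprintf("r%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && runif(1) > p_founder) {
      k <- sample(i - 1L, 2)
      sire[i] <- id[k[1]]
      dam[i] <- if (runif(1) < 0.8) id[k[2]] else NA
    }
  }
  ped <- tc_pedigree(id, sire, dam)
  attr(ped, "sorted") <- TRUE
  ped
}

# --- recursive-kinship oracle (memoized, independent of build_A) --------

oracle_A <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  s <- idx[ped$sire]; s[is.na(s)] <- 0L
  d <- idx[ped$dam];  d[is.na(d)] <- 0L
  memo <- new.env()
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) {
      1 + 0.5 * a(s[[i]], d[[i]])
    } else {
      0.5 * (a(s[[i]], j) + a(d[[i]], j))
    }
    memo[[key]] <- v
    v
  }
  M <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) M[i, j] <- M[j, i] <- a(i, j)
  M
}

# --- dense GLS / PEV oracle ---------------------------------------------
# Operates on a tc_design plus RELATIONSHIP matrices (not inverses):
# KA_rel over design$ids_A, KB_rel over design$ids_B.

oracle_gls <- function(design, vc, KA_rel, KB_rel = NULL) {
  lay <- design$layout
  M <- rbind(as.matrix(design$M_A), as.matrix(design$M_C))
  y <- c(design$y_A, design$y_C)
  nrA <- nrow(design$M_A)
  is_fixed <- lay$effect %in% c("fixedA", "fixedC")
  X <- M[, lay$index[is_fixed], drop = FALSE]
  Zr <- M[, lay$index[!is_fixed], drop = FALSE]
  rl <- lay[!is_fixed, ]

  G0 <- matrix(c(vc$s2A, vc$sAAC, vc$sAAC, vc$s2AC), 2)
  blocks <- list()
  ord <- integer(0)
  if (any(rl$effect == "uAA") && any(rl$effect == "uAC")) {
    nA <- sum(rl$effect == "uAA")
    blocks <- c(blocks, list(kronecker(G0, KA_rel)))
    ord <- c(ord, which(rl$effect == "uAA"), which(rl$effect == "uAC"))
  } else if (any(rl$effect == "uAA")) {
    blocks <- c(blocks, list(vc$s2A * KA_rel))
    ord <- c(ord, which(rl$effect == "uAA"))
  } else if (any(rl$effect == "uAC")) {
    blocks <- c(blocks, list(vc$s2AC * KA_rel))
    ord <- c(ord, which(rl$effect == "uAC"))
  }
  if (any(rl$effect == "uBC")) {
    blocks <- c(blocks, list(vc$s2BC * KB_rel))
    ord <- c(ord, which(rl$effect == "uBC"))
  }
  if (any(rl$effect == "penA")) {
    blocks <- c(blocks, list(diag(vc$s2pA, sum(rl$effect == "penA"))))
    ord <- c(ord, which(rl$effect == "penA"))
  }
  if (any(rl$effect == "penC")) {
    blocks <- c(blocks, list(diag(vc$s2pC, sum(rl$effect == "penC"))))
    ord <- c(ord, which(rl$effect == "penC"))
  }
  Gamma_ord <- as.matrix(Matrix::bdiag(blocks))
  # reorder Gamma back to layout order of Zr columns
  Gamma <- matrix(0, nrow(rl), nrow(rl))
  Gamma[ord, ord] <- Gamma_ord
  Rv <- c(rep(vc$s2eA, nrA), rep(vc$s2eC, length(y) - nrA))
  V <- Zr %*% Gamma %*% t(Zr) + diag(Rv, length(y))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  B <- solve(XtVi %*% X)
  beta <- B %*% XtVi %*% y
  resid <- y - X %*% beta
  u <- Gamma %*% t(Zr) %*% Vi %*% resid
  P <- Vi - t(XtVi) %*% B %*% XtVi
  PEV <- Gamma - Gamma %*% t(Zr) %*% P %*% Zr %*% Gamma
  sol <- numeric(nrow(lay))
  sol[lay$index[is_fixed]] <- as.numeric(beta)
  sol[lay$index[!is_fixed]] <- as.numeric(u)
  pev_full <- rep(NA_real_, nrow(lay))
  pev_full[lay$index[!is_fixed]] <- diag(PEV)
  list(solution = sol, pev = pev_full, layout = lay)
}

# --- tiny terminal-cross toy dataset ------------------------------------
# A hand-sized instance (<= 15 sire-line animals) exercising all effects.

toy_dataset <- function(seed = 1, n_sires = 3, pb_per_sire = 2,
                        cb_per_sire = 2, pen = TRUE) {
  set.seed(seed)
  sires <- sprintf("s%d", seq_len(n_sires))
  damsA <- sprintf("fd%d", seq_len(n_sires))
  pb <- sprintf("p%02d", seq_len(n_sires * pb_per_sire))
  ped_A <- tc_pedigree(
    c(sires, damsA, pb),
    c(rep(NA, 2 * n_sires), rep(sires, each = pb_per_sire)),
    c(rep(NA, 2 * n_sires), rep(damsA, each = pb_per_sire)))
  attr(ped_A, "sorted") <- TRUE
  damsB <- sprintf("b%d", seq_len(n_sires * cb_per_sire))
  ped_B <- tc_pedigree(damsB, NA, NA, line = "dam_line")
  attr(ped_B, "sorted") <- TRUE
  cb <- sprintf("x%02d", seq_len(n_sires * cb_per_sire))
  dat <- rbind(
    data.frame(animal = pb, breed_type = "PB",
               sire = rep(sires, each = pb_per_sire),
               dam = rep(damsA, each = pb_per_sire)),
    data.frame(animal = cb, breed_type = "CB",
               sire = rep(sires, each = cb_per_sire), dam = damsB))
  nrec <- nrow(dat)
  dat$batch <- rep(c("b1", "b2"), length.out = nrec)
  dat$pen <- paste0(dat$batch, ":", dat$breed_type, ":",
                    rep(c("k1", "k2"), each = 2, length.out = nrec))
  dat$start_weight <- round(rnorm(nrec, 35, 3), 2)
  dat$perf <- round(rnorm(nrec, 10, 1), 3)
  recipe <- list(covariates = "start_weight", factors = "batch", pen = pen)
  list(ped_A = ped_A, ped_B = ped_B, data = dat, recipe = recipe,
       sires = sires)
}

toy_vc <- function() {
  tc_vc(s2A = 0.4, sAAC = 0.15, s2AC = 0.2, s2BC = 0.25,
        s2pA = 0.1, s2pC = 0.12, s2eA = 0.8, s2eC = 0.9)
}

# kinship (inverse) pair for a toy, optionally via H with a valid G
toy_kinship <- function(toy, gen = FALSE, seed = 5) {
  KA_rel <- build_A(toy$ped_A)
  KB_rel <- build_A(toy$ped_B)
  if (!gen) {
    return(list(inv = list(A = build_A_inverse(toy$ped_A),
                           B = build_A_inverse(toy$ped_B)),
                rel = list(A = KA_rel, B = KB_rel)))
  }
  set.seed(seed)
  gt <- toy$ped_A$id[grepl("^s|^p", toy$ped_A$id)]
  a22 <- build_A(toy$ped_A, gt)
  n <- length(gt)
  Q <- matrix(rnorm(n * n), n)
  G <- 0.8 * a22 + 0.2 * crossprod(Q) / n
  dimnames(G) <- dimnames(a22)
  Hinv <- build_H_inverse(build_A_inverse(toy$ped_A), a22, G, gt)
  H_rel <- solve(as.matrix(Hinv))  # dense inverse is exact at toy scale
  dimnames(H_rel) <- dimnames(KA_rel)
  list(inv = list(A = Hinv, B = build_A_inverse(toy$ped_B)),
       rel = list(A = H_rel, B = KB_rel), genotyped = gt)
}
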