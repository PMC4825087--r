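# SNP QC, sporadic imputation, Mendelian screening, genomic relationship
# matrix (VanRaden -> Christensen tuning -> blending) and single-step
# H-inverse assembly.

#' Construct a genotype panel
#'
#' Additively coded SNP genotypes: 0 = homozygote for the minor allele,
#' 1 = heterozygote, 2 = homozygote for the other allele, `NA` = missing.
#'
#' @param codes integer matrix (animals x SNPs) with values in
#'   `{0, 1, 2, NA}`; rownames = animal ids, colnames = SNP ids.
#' @return An object of class `tc_panel`.
#' @export
tc_panel <- function(codes) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)) || is.null(colnames(codes))) {
    stop_tc("genotype codes need animal rownames and SNP colnames")
  }
  if (anyDuplicated(rownames(codes)) || anyDuplicated(colnames(codes))) {
    stop_tc("duplicate animal or SNP ids in genotype panel")
  }
  bad <- !(codes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop_tc("genotype codes must be 0, 1, 2 or NA")
  storage.mode(codes) <- "integer"
  structure(list(codes = codes), class = "tc_panel")
}

#' @export
print.tc_panel <- function(x, ...) {
  cat(sprintf("<tc_panel> %d animals x %d SNPs, %.2f%% missing\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Allele frequencies of the genotyped animals
#'
#' Returns, per SNP, the frequency `q` of the allele whose homozygote is
#' coded 0 (the panel's minor allele after QC), computed over non-missing
#' entries: `q = 1 - mean(code)/2`. The minor-allele frequency used for QC
#' is `min(q, 1 - q)`.
#'
#' @param panel a [tc_panel()].
#' @return Named numeric vector `q` with attribute `"maf"`.
#' @export
allele_frequencies <- function(panel) {
  m <- colMeans(panel$codes, na.rm = TRUE)
  q <- 1 - m / 2
  attr(q, "maf") <- pmin(q, 1 - q)
  q
}

#' Quality control of a genotype panel
#'
#' SNPs failing call rate or minor-allele frequency are removed first, then
#' animals failing call rate over the retained SNPs. The operation is
#' idempotent.
#'
#' @param panel a [tc_panel()].
#' @param snp_call_rate minimum SNP call rate (default 0.90).
#' @param maf minimum minor-allele frequency (default 0.05).
#' @param animal_call_rate minimum animal call rate (default 0.90).
#' @return List with elements `panel` (filtered) and `report`
#'   (data.frame of removals: id, type, reason, value).
#' @export
qc_filter <- function(panel, snp_call_rate = 0.90, maf = 0.05,
                      animal_call_rate = 0.90) {
  x <- panel$codes
  if (!length(x)) stop_tc("empty genotype panel")
  report <- data.frame(id = character(0), type = character(0),
                       reason = character(0), value = numeric(0))
  note <- function(id, type, reason, value) {
    rbind(report, data.frame(id = id, type = type, reason = reason,
                             value = value))
  }
  cr_snp <- colMeans(!is.na(x))
  m <- colMeans(x, na.rm = TRUE)
  m[is.nan(m)] <- 0
  maf_snp <- pmin(m / 2, 1 - m / 2)
  drop_cr <- cr_snp < snp_call_rate
  drop_maf <- !drop_cr & maf_snp < maf
  if (any(drop_cr)) {
    report <- note(colnames(x)[drop_cr], "snp", "call_rate", cr_snp[drop_cr])
  }
  if (any(drop_maf)) {
    report <- note(colnames(x)[drop_maf], "snp", "maf", maf_snp[drop_maf])
  }
  x <- x[, !(drop_cr | drop_maf), drop = FALSE]
  if (ncol(x) == 0L) stop_tc("QC removed all SNPs")
  cr_an <- rowMeans(!is.na(x))
  drop_an <- cr_an < animal_call_rate
  if (any(drop_an)) {
    report <- note(rownames(x)[drop_an], "animal", "call_rate", cr_an[drop_an])
  }
  x <- x[!drop_an, , drop = FALSE]
  if (nrow(x) == 0L) stop_tc("QC removed all animals")
  list(panel = tc_panel(x), report = report)
}

#' Impute sporadic missing genotypes
#'
#' Each missing entry is replaced by an independent draw from {0, 1, 2}
#' with Hardy-Weinberg genotype probabilities `(q^2, 2q(1-q), (1-q)^2)` at
#' its locus, where `q` is the frequency of the 0-coded allele among the
#' genotyped animals. Reproducible given `seed`; a panel without missing
#' entries is returned unchanged.
#'
#' @param panel a QC'd [tc_panel()].
#' @param freqs allele frequencies from [allele_frequencies()] (default:
#'   computed from `panel`).
#' @param seed integer seed.
#' @return A complete [tc_panel()].
#' @export
impute_sporadic <- function(panel, freqs = allele_frequencies(panel), seed) {
  x <- panel$codes
  miss <- which(is.na(x))
  if (!length(miss)) return(panel)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  col <- ((miss - 1L) %/% nrow(x)) + 1L
  q <- unname(freqs[colnames(x)])[col]
  u <- runif(length(miss))
  p0 <- q^2
  p1 <- p0 + 2 * q * (1 - q)
  x[miss] <- ifelse(u < p0, 0L, ifelse(u < p1, 1L, 2L))
  tc_panel(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Screen offspring for Mendelian inconsistencies with genotyped parents
#'
#' Counts opposite-homozygote conflicts (offspring 0 vs parent 2 or vice
#' versa) over loci where both genotypes are non-missing, separately per
#' genotyped parent; an animal is flagged when its conflict rate with any
#' genotyped parent exceeds `max_conflict_rate`. Animals without genotyped
#' parents are reported as unchecked.
#'
#' @param panel a [tc_panel()].
#' @param ped a [tc_pedigree()] linking offspring to parents.
#' @param max_conflict_rate flagging threshold (default 0.02).
#' @return List with `flagged` (ids), `unchecked` (ids) and `rates`
#'   (data.frame animal, parent, n_checked, conflict_rate).
#' @export
mendelian_screen <- function(panel, ped, max_conflict_rate = 0.02) {
  x <- panel$codes
  gt <- rownames(x)
  rows <- list()
  for (k in seq_len(nrow(ped))) {
    a <- ped$id[k]
    if (!(a %in% gt)) next
    for (p in c(ped$sire[k], ped$dam[k])) {
      if (is.na(p) || !(p %in% gt)) next
      xa <- x[a, ]; xp <- x[p, ]
      ok <- !is.na(xa) & !is.na(xp)
      conf <- sum((xa == 0L & xp == 2L) | (xa == 2L & xp == 0L), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = a, parent = p, n_checked = sum(ok),
        conflict_rate = if (sum(ok)) conf / sum(ok) else 0)
    }
  }
  rates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal = character(0), parent = character(0),
               n_checked = integer(0), conflict_rate = numeric(0))
  flagged <- unique(rates$animal[rates$conflict_rate > max_conflict_rate])
  unchecked <- setdiff(intersect(ped$id, gt), rates$animal)
  list(flagged = flagged, unchecked = unchecked, rates = rates)
}

#' Raw genomic relationship matrix (VanRaden)
#'
#' `G* = (X - E)(X - E)' / (2 * sum_j q_j (1 - q_j))`, where column j of E
#' is the constant `2 (1 - q_j)` — the mean dosage, so `(X - E)` columns are
#' mean-centered when `q` comes from the same panel.
#'
#' @param panel a complete (post-imputation) [tc_panel()].
#' @param freqs allele frequencies (default: from `panel`).
#' @return Dense symmetric matrix over the genotyped ids, attribute
#'   `stage = "raw"`.
#' @export
compute_G_star <- function(panel, freqs = allele_frequencies(panel)) {
  x <- panel$codes
  if (anyNA(x)) stop_tc("panel has missing genotypes; impute first")
  q <- unname(freqs[colnames(x)])
  if (any(q <= 0 | q >= 1)) {
    stop_tc("monomorphic SNP(s) in panel: ",
            paste(colnames(x)[q <= 0 | q >= 1], collapse = ", "))
  }
  Xc <- sweep(x, 2L, 2 * (1 - q))
  G <- tcrossprod(Xc) / (2 * sum(q * (1 - q)))
  dimnames(G) <- list(rownames(x), rownames(x))
  attr(G, "stage") <- "raw"
  G
}

#' Tune G* to the pedigree submatrix and blend
#'
#' First solves for scalars (alpha, beta) so that the tuned matrix
#' `beta * G* + alpha * J` matches both the overall mean and the diagonal
#' mean of `A22` (the adjustment of Christensen et al.), then blends:
#' `G = w * G_tuned + (1 - w) * A22` with `w = blend_weight`, which makes
#' G safely invertible.
#'
#' @param gstar raw genomic matrix from [compute_G_star()].
#' @param a22 pedigree relationship matrix of the genotyped animals, same
#'   id order.
#' @param blend_weight weight on the tuned genomic matrix (default 0.95).
#' @return Blended matrix with attributes `alpha`, `beta`, `kappa`
#'   (2-norm condition number) and `stage = "blended"`.
#' @export
tune_and_blend <- function(gstar, a22, blend_weight = 0.95) {
  if (!identical(rownames(gstar), rownames(a22))) {
    stop_tc("gstar and a22 must share the same id order")
  }
  a22 <- as.matrix(a22)
  mg <- mean(gstar); mdg <- mean(diag(gstar))
  ma <- mean(a22);   mda <- mean(diag(a22))
  if (abs(mdg - mg) < 1e-12) {
    stop_tc("degenerate tuning system: mean(diag G*) == mean(G*) (",
            format(mdg), "); G* carries no inbreeding contrast")
  }
  beta <- (mda - ma) / (mdg - mg)
  alpha <- ma - beta * mg
  Gt <- beta * gstar + alpha
  G <- blend_weight * Gt + (1 - blend_weight) * a22
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  kappa <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (!is.finite(kappa)) {
    warning("blended G is numerically singular (condition number not finite)")
  }
  attr(G, "alpha") <- alpha
  attr(G, "beta") <- beta
  attr(G, "kappa") <- kappa
  attr(G, "stage") <- "blended"
  G
}

#' Assemble the single-step H-inverse
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G^-1 - A22^-1]]`: the genotyped block of the
#' sparse pedigree inverse is augmented with the difference between the
#' genomic and pedigree-submatrix inverses; all other entries are untouched.
#'
#' @param a_inv sparse pedigree inverse from [build_A_inverse()].
#' @param a22 pedigree relationships of the genotyped animals (id order =
#'   `genotyped_ids`).
#' @param g blended genomic matrix (same order).
#' @param genotyped_ids ids of the genotyped animals.
#' @return Sparse symmetric Matrix with attribute `genotyped`.
#' @export
build_H_inverse <- function(a_inv, a22, g, genotyped_ids) {
  ids <- rownames(a_inv)
  if (!all(genotyped_ids %in% ids)) {
    stop_tc("genotyped id(s) not in pedigree inverse: ",
            paste(setdiff(genotyped_ids, ids), collapse = ", "))
  }
  Hinv <- methods::as(methods::as(a_inv, "generalMatrix"), "CsparseMatrix")
  if (length(genotyped_ids)) {
    g <- as.matrix(g)
    a22 <- as.matrix(a22)
    stopifnot(identical(rownames(g), genotyped_ids),
              identical(rownames(a22), genotyped_ids))
    evg <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(evg) < 1e-10 * max(evg)) {
      stop_tc("G is numerically singular (condition number ",
              format(max(evg) / max(min(evg), 0)), ")")
    }
    Ginv <- solve(g)
    A22inv <- solve(a22)
    D <- (Ginv + t(Ginv)) / 2 - (A22inv + t(A22inv)) / 2
    idx <- match(genotyped_ids, ids)
    Hinv[idx, idx] <- Hinv[idx, idx] + D
  }
  Hinv <- methods::as(Matrix::drop0(Hinv), "CsparseMatrix")
  attr(Hinv, "genotyped") <- genotyped_ids
  Hinv
}

#' Read / write genotype files
#'
#' Whitespace- or tab-delimited text: a header row of SNP ids, then one row
#' per animal (animal id followed by p codes); `NA` marks missing. The
#' transposed layout (one row per SNP) is supported via `transposed = TRUE`.
#'
#' @param path file path.
#' @param transposed logical; is the file SNP-major?
#' @return A [tc_panel()] (reader); `path` invisibly (writer).
#' @export
read_genotypes <- function(path, transposed = FALSE) {
  if (!file.exists(path)) stop_tc("genotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (transposed) m <- t(m)
  tc_panel(m)
}

#' @rdname read_genotypes
#' @param panel a [tc_panel()].
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(animal = rownames(panel$codes), panel$codes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
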