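# SNP QC, imputation, Mendelian screening, G construction and H-inverse.

make_panel <- function(m) {
  rownames(m) <- sprintf("a%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("snp%d", seq_len(ncol(m)))
  tc_panel(m)
}

test_that("qc_filter removes SNPs by call rate / MAF, then animals,
           and is idempotent", {
  set.seed(1)
  # 4 SNPs with MAF 0.50, 0.04, 0.20, 0.00 on complete data (50 animals)
  n <- 50
  col_for_maf <- function(maf) {
    x <- rbinom(n, 2, 1 - maf)
    # force the exact frequency by adjusting counts
    need <- round(2 * n * (1 - maf)) - sum(x)
    while (need != 0) {
      i <- sample(n, 1)
      if (need > 0 && x[i] < 2) { x[i] <- x[i] + 1L; need <- need - 1 }
      if (need < 0 && x[i] > 0) { x[i] <- x[i] - 1L; need <- need + 1 }
    }
    x
  }
  m <- cbind(col_for_maf(0.5), col_for_maf(0.04), col_for_maf(0.2),
             col_for_maf(0))
  qc <- qc_filter(make_panel(m))
  expect_identical(colnames(qc$panel$codes), c("snp1", "snp3"))
  expect_setequal(qc$report$id[qc$report$reason == "maf"], c("snp2", "snp4"))

  # SNP with 85% call rate removed regardless of MAF
  m2 <- matrix(1L, 40, 2)
  m2[, 2] <- rbinom(40, 2, 0.5)
  m2[1:6, 1] <- NA  # 85% call rate
  qc2 <- qc_filter(make_panel(m2))
  expect_identical(colnames(qc2$panel$codes), "snp2")

  # animal missing 15% of retained SNPs removed
  m3 <- matrix(rbinom(20 * 20, 2, 0.5), 20, 20)
  m3[1, 1:3] <- NA  # 85% call rate for animal 1
  qc3 <- qc_filter(make_panel(m3))
  expect_false("a1" %in% rownames(qc3$panel$codes))

  # idempotence
  qc4 <- qc_filter(qc3$panel)
  expect_identical(qc4$panel$codes, qc3$panel$codes)
  expect_equal(nrow(qc4$report), 0)

  # all SNPs removed -> error
  expect_error(qc_filter(make_panel(matrix(0L, 10, 2))), "all SNPs")
})

test_that("impute_sporadic draws Hardy-Weinberg genotypes reproducibly", {
  set.seed(2)
  complete <- make_panel(matrix(rbinom(200, 2, 0.5), 20, 10))
  expect_identical(impute_sporadic(complete, seed = 1)$codes,
                   complete$codes)

  # q = 0.5 locus with 10,000 missing entries: mean code ~ 1.0, SE ~ 0.007
  m <- matrix(rep(c(0L, 1L, 1L, 2L), 5000), ncol = 2)  # both cols q = 0.5
  m2 <- rbind(m, matrix(NA_integer_, 10000, 2))
  panel <- make_panel(m2)
  imp <- impute_sporadic(panel,
                         setNames(rep(0.5, 2), colnames(panel$codes)),
                         seed = 7)
  filled <- imp$codes[10001:20000, 1]
  expect_equal(mean(filled), 1.0, tolerance = 3 * 0.007)
  expect_false(anyNA(imp$codes))

  # determinism: same seed twice -> identical panels
  expect_identical(impute_sporadic(panel, seed = 42)$codes,
                   impute_sporadic(panel, seed = 42)$codes)
  expect_false(identical(impute_sporadic(panel, seed = 42)$codes,
                         impute_sporadic(panel, seed = 43)$codes))
})

test_that("mendelian_screen flags opposite-homozygote conflicts", {
  ped <- tc_pedigree(c("sire", "kid1", "kid2", "kid3"),
                     c(NA, "sire", "sire", NA), c(NA, NA, NA, NA))
  attr(ped, "sorted") <- TRUE
  p <- 100
  sire <- rep(2L, p)
  kid1 <- sire                      # identical to sire: no conflicts
  kid2 <- sire; kid2[1:10] <- 0L    # 10% opposite homozygotes
  kid3 <- rep(1L, p)                # no genotyped parents
  m <- rbind(sire = sire, kid1 = kid1, kid2 = kid2, kid3 = kid3)
  colnames(m) <- sprintf("s%d", 1:p)
  panel <- tc_panel(m)
  scr <- mendelian_screen(panel, ped, max_conflict_rate = 0.05)
  expect_identical(scr$flagged, "kid2")
  expect_true("kid3" %in% scr$unchecked)
  expect_equal(scr$rates$conflict_rate[scr$rates$animal == "kid1"], 0)
})

test_that("compute_G_star follows the VanRaden formula", {
  # single SNP, q = 0.5, codes (0, 2): centered (-1, 1), denom 0.5
  m <- matrix(c(0L, 2L), 2, 1)
  panel <- make_panel(m)
  G <- compute_G_star(panel)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # centering identity: row means of (X - E) are 0 when q comes from the
  # same panel, so G* rows sum to 0 against the all-ones vector
  set.seed(3)
  big <- make_panel(matrix(rbinom(30 * 200, 2, runif(200, .1, .9)),
                           30, 200, byrow = FALSE))
  Gb <- compute_G_star(big)
  expect_lt(max(abs(rowMeans(Gb))), 1e-10)

  # duplicated animal -> identical rows/columns
  dup <- big$codes
  dup[2, ] <- dup[1, ]
  Gd <- compute_G_star(make_panel(dup))
  expect_equal(Gd[1, ], Gd[2, ], ignore_attr = "names")

  # monomorphic SNP rejected
  mono <- big$codes
  mono[, 1] <- 2L
  expect_error(compute_G_star(make_panel(mono)), "monomorphic")

  # missing entries rejected
  holes <- big$codes
  holes[1, 1] <- NA
  expect_error(compute_G_star(make_panel(holes)), "impute")
})

test_that("tune_and_blend matches both A22 means exactly, then blends", {
  set.seed(4)
  ped <- random_pedigree(40, 21)
  gt <- ped$id[20:40]
  a22 <- build_A(ped, gt)
  n <- length(gt)
  Q <- matrix(rnorm(n * 2 * n), n)
  Gs <- tcrossprod(Q) / (2 * n)
  dimnames(Gs) <- dimnames(a22)

  G <- tune_and_blend(Gs, a22, blend_weight = 0.95)
  a <- attr(G, "alpha"); b <- attr(G, "beta")
  Gt <- b * Gs + a
  expect_lt(abs(mean(diag(Gt)) - mean(diag(a22))), 1e-10)
  expect_lt(abs(mean(Gt) - mean(a22)), 1e-10)
  expect_equal(unname(G), unname(0.95 * Gt + 0.05 * a22),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(is.finite(attr(G, "kappa")))

  # G* already matching both means: tuning is the identity
  G2 <- tune_and_blend(Gt, a22, blend_weight = 1)
  expect_equal(attr(G2, "alpha"), 0, tolerance = 1e-10)
  expect_equal(attr(G2, "beta"), 1, tolerance = 1e-10)

  # blend_weight = 1 with singular tuned G: condition warning surfaces
  v <- rnorm(n)
  rank1 <- tcrossprod(v)  # tuned version is rank <= 2, singular for n > 2
  dimnames(rank1) <- dimnames(a22)
  expect_warning(tune_and_blend(rank1, a22, blend_weight = 1), "singular")

  # degenerate tuning system rejected
  ones <- matrix(1, n, n, dimnames = dimnames(a22))
  expect_error(tune_and_blend(ones, a22), "degenerate")
})

test_that("build_H_inverse augments only the genotyped block", {
  ped <- random_pedigree(30, 22)
  Ainv <- build_A_inverse(ped)
  gt <- ped$id[21:30]
  a22 <- build_A(ped, gt)

  # G = A22 exactly: H^-1 = A^-1
  H1 <- build_H_inverse(Ainv, a22, a22, gt)
  expect_lt(max(abs(as.matrix(H1) - as.matrix(Ainv))), 1e-8)

  # empty genotyped set: H^-1 = A^-1
  H0 <- build_H_inverse(Ainv, a22[0, 0], a22[0, 0], character(0))
  expect_equal(as.matrix(H0), as.matrix(Ainv), tolerance = 1e-12)

  # random valid G: dense inverse of the implied H equals H^-1's inverse
  set.seed(5)
  Q <- matrix(rnorm(10 * 30), 10)
  G <- 0.7 * a22 + 0.3 * tcrossprod(Q) / 30
  dimnames(G) <- dimnames(a22)
  Hinv <- build_H_inverse(Ainv, a22, G, gt)
  A <- build_A(ped)
  # H from the standard partitioned identity: H22 = G
  idx <- match(gt, ped$id)
  A22i <- solve(A[idx, idx])
  H <- A
  H[-idx, -idx] <- A[-idx, -idx] +
    A[-idx, idx] %*% A22i %*% (G - A[idx, idx]) %*% A22i %*% A[idx, -idx]
  H[-idx, idx] <- A[-idx, idx] %*% A22i %*% G
  H[idx, -idx] <- t(H[-idx, idx])
  H[idx, idx] <- G
  expect_lt(max(abs(solve(as.matrix(Hinv)) - H)), 1e-6)

  # non-genotyped block untouched
  expect_equal(as.matrix(Hinv)[-idx, -idx], as.matrix(Ainv)[-idx, -idx],
               tolerance = 1e-12)

  # singular G rejected with a condition-number message
  sing <- a22
  sing[, ] <- 1
  expect_error(build_H_inverse(Ainv, a22, sing, gt), "singular")
})

test_that("genotype files round-trip, including the transposed layout", {
  set.seed(6)
  m <- matrix(rbinom(50, 2, 0.4), 10, 5)
  m[2, 3] <- NA
  panel <- make_panel(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(panel, f)
  back <- read_genotypes(f)
  expect_identical(back$codes, panel$codes)

  # transposed: rows = SNPs
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(snp = colnames(panel$codes), t(panel$codes),
                   check.names = FALSE)
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_genotypes(tf, transposed = TRUE)
  expect_identical(back2$codes, panel$codes)
})
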