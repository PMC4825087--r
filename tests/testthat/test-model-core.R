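# Design construction, mixed-model equations, BLUP, PEV/accuracy,
# gametic rescaling, candidate selection and masking.

test_that("build_design lays out effects per the recipe and model kind", {
  toy <- toy_dataset(1)
  spec <- model_spec("PED", "perf", recipe = toy$recipe)
  des <- build_design(toy$data, spec, toy$ped_A, toy$ped_B)
  lay <- des$layout
  # two genetic effects per sire-line animal
  expect_equal(sum(lay$effect == "uAA"), nrow(toy$ped_A))
  expect_equal(sum(lay$effect == "uAC"), nrow(toy$ped_A))
  expect_equal(sum(lay$effect == "uBC"), nrow(toy$ped_B))
  # CB half sibs sharing a sire: that sire's uAC column has one 1 per record
  j <- lay$index[lay$effect == "uAC" & lay$level == "s1"]
  expect_equal(sum(des$M_C[, j]), 2)
  expect_true(all(des$M_C[, j] %in% c(0, 1)))
  # PB record loads exactly one 1 in uAA
  jA <- lay$index[lay$effect == "uAA"]
  expect_true(all(Matrix::rowSums(des$M_A[, jA]) == 1))

  # pen off: no pen block
  toy2 <- toy_dataset(2, pen = FALSE)
  rec2 <- toy2$recipe; rec2$pen <- FALSE
  des2 <- build_design(toy2$data, model_spec("PED", "perf", recipe = rec2),
                       toy2$ped_A, toy2$ped_B)
  expect_false(any(des2$layout$effect %in% c("penA", "penC")))

  # univariate kinds use only their records and genetic blocks
  desU <- build_design(toy$data, model_spec("GEN_UNI_PB", "perf",
                                            recipe = toy$recipe),
                       toy$ped_A, toy$ped_B)
  expect_equal(nrow(desU$M_C), 0)
  expect_false(any(desU$layout$effect %in% c("uAC", "uBC")))
  desC <- build_design(toy$data, model_spec("GEN_UNI_CB", "perf",
                                            recipe = toy$recipe),
                       toy$ped_A, toy$ped_B)
  expect_equal(nrow(desC$M_A), 0)
  expect_false(any(desC$layout$effect == "uAA"))

  # CB record with dam outside the dam line is rejected
  bad <- toy$data
  bad$dam[bad$breed_type == "CB"][1] <- "stranger"
  expect_error(build_design(bad, spec, toy$ped_A, toy$ped_B), "stranger")
})

test_that("Table-style trait recipes select the documented effects", {
  # meat-quality recipe: slaughter-weight covariate, slaughter date +
  # batch factors, no pen
  r <- trait_recipe("ph")
  expect_equal(r$covariates, "slaughter_weight")
  expect_setequal(r$factors, c("slaughter_date", "batch"))
  expect_false(r$pen)
  # growth recipe: start weight + batch + pen
  r2 <- trait_recipe("adg")
  expect_equal(r2$covariates, "start_weight")
  expect_true(r2$pen)
  # carcass recipe uses hot-carcass weight
  expect_equal(trait_recipe("lm")$covariates, "carcass_weight")
  expect_error(trait_recipe("nope"), "unknown trait")
})

test_that("solve_blup matches the dense GLS oracle on toy instances
           for all four model kinds", {
  for (seed in 1:3) {
    toy <- toy_dataset(seed)
    vc <- toy_vc()
    for (gen in c(FALSE, TRUE)) {
      kin <- toy_kinship(toy, gen = gen, seed = seed + 10)
      for (kind in c(if (gen) c("GEN", "GEN_UNI_PB", "GEN_UNI_CB")
                     else "PED")) {
        spec <- model_spec(kind, "perf", recipe = toy$recipe)
        des <- build_design(toy$data, spec, toy$ped_A, toy$ped_B)
        fit <- solve_blup(assemble_mme(des, vc, kin$inv))
        orc <- oracle_gls(des, vc, kin$rel$A, kin$rel$B)
        expect_lt(max(abs(unname(fit$solution) - orc$solution)), 1e-8,
                  label = paste("solutions", kind, "seed", seed))
      }
    }
  }
})

test_that("compute_accuracy matches the dense PEV oracle and the R formula", {
  toy <- toy_dataset(4)
  vc <- toy_vc()
  kin <- toy_kinship(toy)
  spec <- model_spec("PED", "perf", recipe = toy$recipe)
  des <- build_design(toy$data, spec, toy$ped_A, toy$ped_B)
  fit <- solve_blup(assemble_mme(des, vc, kin$inv))
  Fv <- compute_inbreeding(toy$ped_A)
  anim <- toy$ped_A$id
  targets <- data.frame(animal = rep(anim, 2),
                        performance = rep(c("PB", "CB"), each = length(anim)))
  rep_ <- compute_accuracy(fit, targets, Fv, data = toy$data)
  orc <- oracle_gls(des, vc, kin$rel$A, kin$rel$B)
  lay <- des$layout
  pev_orc <- vapply(seq_len(nrow(targets)), function(r) {
    block <- if (targets$performance[r] == "PB") "uAA" else "uAC"
    orc$pev[lay$index[lay$effect == block & lay$level == targets$animal[r]]]
  }, numeric(1))
  expect_lt(max(abs(rep_$pev - pev_orc)), 1e-8)
  s2k <- ifelse(targets$performance == "PB", vc$s2A, vc$s2AC)
  expect_equal(rep_$accuracy,
               sqrt(pmax(0, 1 - rep_$pev / ((1 + rep_$f) * s2k))))
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))
  expect_true(all(rep_$pev <= (1 + rep_$f) * s2k + 1e-10))
  # phenotyped animals are flagged
  expect_true(all(rep_$own_record[rep_$animal %in% toy$data$animal &
                                    rep_$performance == "PB"] ==
                    (rep_$animal[rep_$animal %in% toy$data$animal &
                                   rep_$performance == "PB"] %in%
                       toy$data$animal[toy$data$breed_type == "PB"])))

  # isolated founder with no records: PEV = s2k, R = 0
  lone <- tc_pedigree("lone", NA, NA)
  attr(lone, "sorted") <- TRUE
  dat1 <- toy$data[toy$data$breed_type == "PB", ][1, ]
  dat1$animal <- "lone"; dat1$sire <- NA; dat1$dam <- NA
  dat1$perf <- NA  # no usable record
  # use a 2-animal pedigree so the design has at least one record
  ped2 <- tc_pedigree(c("lone", "rec"), c(NA, NA), c(NA, NA))
  attr(ped2, "sorted") <- TRUE
  datr <- data.frame(animal = "rec", breed_type = "PB", sire = NA, dam = NA,
                     batch = "b1", pen = "b1:PB:k1", start_weight = 35,
                     perf = 10)
  rec0 <- list(covariates = character(0), factors = character(0), pen = FALSE)
  desL <- build_design(datr, model_spec("GEN_UNI_PB", "perf", recipe = rec0),
                       ped2)
  fitL <- solve_blup(assemble_mme(desL, vc, list(A = build_A_inverse(ped2))))
  repL <- compute_accuracy(fitL, data.frame(animal = "lone",
                                            performance = "PB"),
                           setNames(0, "lone"))
  expect_equal(repL$pev, vc$s2A, tolerance = 1e-10)
  expect_equal(repL$accuracy, 0)
})

test_that("model-collapse equivalences hold", {
  toy <- toy_dataset(5)
  vc <- toy_vc()
  kin <- toy_kinship(toy)

  # GEN with G = A22 gives the same coefficient matrix as PED
  gt <- toy$ped_A$id[grepl("^s|^p", toy$ped_A$id)]
  a22 <- build_A(toy$ped_A, gt)
  Hinv_eq <- build_H_inverse(kin$inv$A, a22, a22, gt)
  des <- build_design(toy$data, model_spec("GEN", "perf",
                                           recipe = toy$recipe),
                      toy$ped_A, toy$ped_B)
  mme_gen <- assemble_mme(des, vc, list(A = Hinv_eq, B = kin$inv$B))
  desP <- build_design(toy$data, model_spec("PED", "perf",
                                            recipe = toy$recipe),
                       toy$ped_A, toy$ped_B)
  mme_ped <- assemble_mme(desP, vc, kin$inv)
  expect_lt(max(abs(mme_matrix(mme_gen) - mme_matrix(mme_ped))), 1e-8)

  # sAAC = 0: bivariate solutions equal the concatenated univariate fits
  vc0 <- tc_vc(vc$s2A, 0, vc$s2AC, vc$s2BC, vc$s2pA, vc$s2pC,
               vc$s2eA, vc$s2eC)
  fitB <- solve_blup(assemble_mme(desP, vc0, kin$inv))
  desU1 <- build_design(toy$data, model_spec("GEN_UNI_PB", "perf",
                                             recipe = toy$recipe),
                        toy$ped_A, toy$ped_B)
  fitU1 <- solve_blup(assemble_mme(desU1, vc0, kin$inv))
  desU2 <- build_design(toy$data, model_spec("GEN_UNI_CB", "perf",
                                             recipe = toy$recipe),
                        toy$ped_A, toy$ped_B)
  fitU2 <- solve_blup(assemble_mme(desU2, vc0, kin$inv))
  expect_equal(unname(fit_effect(fitB, "uAA")),
               unname(fit_effect(fitU1, "uAA")), tolerance = 1e-8)
  expect_equal(unname(fit_effect(fitB, "uAC")),
               unname(fit_effect(fitU2, "uAC")), tolerance = 1e-8)
  expect_equal(unname(fit_effect(fitB, "uBC")),
               unname(fit_effect(fitU2, "uBC")), tolerance = 1e-8)

  # scale invariance: doubling every variance leaves BLUP unchanged
  vc2 <- tc_vc(2 * vc$s2A, 2 * vc$sAAC, 2 * vc$s2AC, 2 * vc$s2BC,
               2 * vc$s2pA, 2 * vc$s2pC, 2 * vc$s2eA, 2 * vc$s2eC)
  expect_equal(unname(solve_blup(assemble_mme(desP, vc2, kin$inv))$solution),
               unname(solve_blup(assemble_mme(desP, vc, kin$inv))$solution),
               tolerance = 1e-8)
})

test_that("accuracy never decreases when a record is added, and masking
           never increases a candidate's accuracy", {
  toy <- toy_dataset(6)
  vc <- toy_vc()
  kin <- toy_kinship(toy)
  spec <- model_spec("PED", "perf", recipe = toy$recipe)
  Fv <- compute_inbreeding(toy$ped_A)
  anim <- toy$ped_A$id
  targets <- data.frame(animal = rep(anim, 2),
                        performance = rep(c("PB", "CB"), each = length(anim)))

  acc_for <- function(dat) {
    des <- build_design(dat, spec, toy$ped_A, toy$ped_B)
    fit <- solve_blup(assemble_mme(des, vc, kin$inv))
    compute_accuracy(fit, targets, Fv)$accuracy
  }
  full <- acc_for(toy$data)
  # drop one PB record: no animal's accuracy may increase
  dropped <- toy$data[-1, ]
  less <- acc_for(dropped)
  expect_true(all(less <= full + 1e-10))
  # mask a candidate
  cand <- select_candidates(toy$ped_A, toy$data)[1]
  masked <- acc_for(mask_phenotypes(toy$data, cand))
  expect_true(all(masked <= full + 1e-10))
  i <- which(targets$animal == cand & targets$performance == "PB")
  expect_lt(masked[i], full[i])
})

test_that("rescale_gametic doubles solutions, quadruples gametic variances,
           preserves rg, and refuses double application", {
  vc <- tc_vc(s2A = 1.0, sAAC = 1.0, s2AC = 2.5, s2BC = 0.5,
              s2eA = 1, s2eC = 1)
  out <- rescale_gametic(vc)
  expect_equal(out$s2AC, 10)
  expect_equal(out$sAAC, 2.0)
  expect_equal(out$s2BC, 2.0)
  expect_equal(rg_of(out), rg_of(vc))
  expect_equal(rg_of(vc), 1 / sqrt(2.5))
  expect_error(rescale_gametic(out), "twice")

  u <- structure(c(a = 0, b = 1.5), scale = "gametic")
  u2 <- rescale_gametic(u)
  expect_equal(unname(u2), c(0, 3), ignore_attr = TRUE)
  expect_error(rescale_gametic(u2), "twice")
})

test_that("select_candidates applies the offspring-count rule", {
  dat <- data.frame(
    animal = c(paste0("o", 1:3), paste0("q", 1:4), paste0("z", 1:5)),
    breed_type = "PB",
    sire = c(rep("sA", 3), rep("sB", 4), rep("sC", 5)),
    dam = NA)
  cand <- select_candidates(NULL, dat)
  expect_equal(sum(startsWith(cand, "o")), 1)  # 3 offspring -> 1
  expect_equal(sum(startsWith(cand, "q")), 2)  # 4 offspring -> 2
  expect_equal(sum(startsWith(cand, "z")), 2)
  # deterministic: lexicographic
  expect_true(all(c("o1", "q1", "q2") %in% cand))
  # 90 sires with >= 4 offspring -> 180 candidates
  big <- data.frame(animal = paste0("a", 1:360), breed_type = "PB",
                    sire = rep(paste0("s", 1:90), each = 4), dam = NA)
  expect_length(select_candidates(NULL, big), 180)
})

test_that("mask_phenotypes removes records but not pedigree presence", {
  toy <- toy_dataset(7)
  expect_identical(mask_phenotypes(toy$data, character(0)), toy$data)
  m <- mask_phenotypes(toy$data, "p01")
  expect_false("p01" %in% m$animal)
  expect_equal(nrow(m), nrow(toy$data) - 1)
  # masking almost everything still solves under a mean-only recipe
  keep <- toy$data[toy$data$breed_type == "CB", ][1, ]
  rec0 <- list(covariates = character(0), factors = character(0),
               pen = FALSE)
  des <- build_design(keep, model_spec("PED", "perf", recipe = rec0),
                      toy$ped_A, toy$ped_B)
  fit <- solve_blup(assemble_mme(des, toy_vc(), toy_kinship(toy)$inv))
  expect_true(all(is.finite(fit$solution)))
  # with the full recipe, one record cannot support the covariate slope:
  # the rank-deficiency error names the confounded effect
  desF <- build_design(keep, model_spec("PED", "perf",
                                        recipe = toy$recipe),
                       toy$ped_A, toy$ped_B)
  expect_error(
    suppressWarnings(solve_blup(assemble_mme(desF, toy_vc(),
                                             toy_kinship(toy)$inv))),
    "positive definite")
})
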