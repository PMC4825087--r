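# Trait tables, per-trait fixed-effect recipes and design-matrix
# construction over a global equation layout.

#' Per-trait systematic-effect recipes
#'
#' Which covariates, cross-classified factors and pen effect enter the
#' model for each trait. The six station traits follow the study design
#' (growth traits: start-of-test weight + batch + pen; carcass: hot-carcass
#' weight + batch + pen; meat-quality traits: slaughter weight +
#' slaughter date + batch, no pen). `"perf"` is the synthetic trait.
#'
#' @param trait one of `"adg"`, `"fcr"`, `"lm"`, `"ph"`, `"dl"`, `"imf"`,
#'   `"perf"`.
#' @return List with `covariates`, `factors`, `pen`.
#' @export
trait_recipe <- function(trait) {
  r <- switch(tolower(trait),
    adg  = list(covariates = "start_weight", factors = "batch", pen = TRUE),
    fcr  = list(covariates = "start_weight", factors = "batch", pen = TRUE),
    lm   = list(covariates = "carcass_weight", factors = "batch", pen = TRUE),
    ph   = list(covariates = "slaughter_weight",
                factors = c("slaughter_date", "batch"), pen = FALSE),
    dl   = list(covariates = "slaughter_weight",
                factors = c("slaughter_date", "batch"), pen = FALSE),
    imf  = list(covariates = "slaughter_weight",
                factors = c("slaughter_date", "batch"), pen = FALSE),
    perf = list(covariates = "start_weight", factors = "batch", pen = TRUE),
    NULL)
  if (is.null(r)) stop_tc("unknown trait: ", trait,
                          " (pass a custom recipe to model_spec)")
  r
}

#' Model specification
#'
#' @param kind one of `"PED"`, `"GEN"`, `"GEN_UNI_PB"`, `"GEN_UNI_CB"`.
#'   PED and GEN are the bivariate terminal-cross models (pedigree-only vs
#'   single-step); the GEN_UNI variants use only purebred or only crossbred
#'   records.
#' @param trait trait name (selects the recipe) — the phenotype column of
#'   the trait table.
#' @param recipe systematic-effect recipe, defaults to
#'   [trait_recipe()]`(trait)`.
#' @param genotyped ids of genotyped animals (GEN variants; informational).
#' @return An object of class `tc_model_spec`.
#' @export
model_spec <- function(kind = c("PED", "GEN", "GEN_UNI_PB", "GEN_UNI_CB"),
                       trait, recipe = trait_recipe(trait),
                       genotyped = character(0)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, trait = trait, recipe = recipe,
                 genotyped = genotyped),
            class = "tc_model_spec")
}

.uses_pb <- function(kind) kind %in% c("PED", "GEN", "GEN_UNI_PB")
.uses_cb <- function(kind) kind %in% c("PED", "GEN", "GEN_UNI_CB")
.bivariate <- function(kind) kind %in% c("PED", "GEN")

#' Validate a trait table
#'
#' A trait table holds one record per phenotyped animal: `animal`,
#' `breed_type` (`"PB"`/`"CB"`), `sire`, `dam`, the systematic-effect
#' columns used by the recipe, and one column per trait.
#'
#' @param data data.frame.
#' @param trait trait column that must be present.
#' @return `data`, invisibly; errors describe the first violation.
#' @export
validate_trait_table <- function(data, trait = NULL) {
  need <- c("animal", "breed_type", "sire", "dam")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_tc("trait table lacks column(s): ",
                            paste(miss, collapse = ", "))
  if (!all(data$breed_type %in% c("PB", "CB"))) {
    stop_tc("breed_type must be 'PB' or 'CB'")
  }
  if (!is.null(trait) && !(trait %in% names(data))) {
    stop_tc("trait column not found: ", trait)
  }
  invisible(data)
}

#' Build design matrices for a terminal-cross model
#'
#' Constructs the record-by-equation incidence matrices over a global
#' equation layout: separate fixed-effect blocks for PB and CB records
#' (intercept, drop-first factor contrasts, mean-centered covariates),
#' random pen blocks, and the genetic blocks: `u_AA` and `u_AC` each cover
#' every sire-line pedigree animal (two genetic effects per purebred
#' animal), `u_BC` covers every dam-line animal. A purebred record loads 1
#' on its own `u_AA`; a crossbred record loads 1 on its sire's `u_AC` and
#' its dam's `u_BC` (gametic, unit incidence).
#'
#' @param data trait table (see [validate_trait_table()]).
#' @param spec a [model_spec()].
#' @param ped_A sorted sire-line [tc_pedigree()].
#' @param ped_B sorted dam-line [tc_pedigree()] (bivariate / CB kinds).
#' @return An object of class `tc_design`.
#' @export
build_design <- function(data, spec, ped_A, ped_B = NULL) {
  validate_trait_table(data, spec$trait)
  kind <- spec$kind
  rec <- spec$recipe
  y_all <- data[[spec$trait]]
  data <- data[!is.na(y_all), , drop = FALSE]

  dat_A <- data[data$breed_type == "PB", , drop = FALSE]
  dat_C <- data[data$breed_type == "CB", , drop = FALSE]
  if (!.uses_pb(kind)) dat_A <- dat_A[0, , drop = FALSE]
  if (!.uses_cb(kind)) dat_C <- dat_C[0, , drop = FALSE]

  if (nrow(dat_A) && !all(dat_A$animal %in% ped_A$id)) {
    stop_tc("PB record animal(s) not in sire-line pedigree: ",
            paste(setdiff(dat_A$animal, ped_A$id), collapse = ", "))
  }
  if (nrow(dat_C)) {
    if (is.null(ped_B)) stop_tc("CB records present but ped_B missing")
    if (!all(dat_C$sire %in% ped_A$id)) {
      stop_tc("CB record sire(s) not in sire-line pedigree: ",
              paste(setdiff(dat_C$sire, ped_A$id), collapse = ", "))
    }
    if (!all(dat_C$dam %in% ped_B$id)) {
      stop_tc("CB record dam(s) not in dam-line pedigree: ",
              paste(setdiff(dat_C$dam, ped_B$id), collapse = ", "))
    }
  }

  # --- equation layout -------------------------------------------------
  eff <- character(0); lev <- character(0)
  add_block <- function(effect, levels) {
    eff <<- c(eff, rep(effect, length(levels)))
    lev <<- c(lev, as.character(levels))
  }
  fixed_levels <- function(dat, tag) {
    if (!nrow(dat)) return(list(names = character(0), build = NULL))
    nm <- "(Intercept)"
    fls <- list()
    for (f in rec$factors) {
      if (!(f %in% names(dat))) stop_tc("missing factor column: ", f)
      if (anyNA(dat[[f]])) stop_tc("NA in factor column: ", f)
      ls <- sort(unique(as.character(dat[[f]])))
      fls[[f]] <- ls
      if (length(ls) > 1) nm <- c(nm, paste0(f, "=", ls[-1]))
    }
    ctr <- list()
    for (cv in rec$covariates) {
      if (!(cv %in% names(dat))) stop_tc("missing covariate column: ", cv)
      if (anyNA(dat[[cv]])) stop_tc("NA in covariate column: ", cv)
      ctr[[cv]] <- mean(dat[[cv]])
      nm <- c(nm, paste0("cov:", cv))
    }
    list(names = nm, factor_levels = fls, centers = ctr)
  }
  fxA <- fixed_levels(dat_A, "A")
  fxC <- fixed_levels(dat_C, "C")
  if (length(fxA$names)) add_block("fixedA", fxA$names)
  if (length(fxC$names)) add_block("fixedC", fxC$names)

  penA_lev <- if (isTRUE(rec$pen) && nrow(dat_A)) {
    if (anyNA(dat_A$pen)) stop_tc("NA in pen column (PB records)")
    sort(unique(as.character(dat_A$pen)))
  } else character(0)
  penC_lev <- if (isTRUE(rec$pen) && nrow(dat_C)) {
    if (anyNA(dat_C$pen)) stop_tc("NA in pen column (CB records)")
    sort(unique(as.character(dat_C$pen)))
  } else character(0)
  if (length(penA_lev)) add_block("penA", penA_lev)
  if (length(penC_lev)) add_block("penC", penC_lev)

  ids_A <- ped_A$id
  ids_B <- if (!is.null(ped_B)) ped_B$id else character(0)
  has_uAA <- kind %in% c("PED", "GEN", "GEN_UNI_PB")
  has_uAC <- kind %in% c("PED", "GEN", "GEN_UNI_CB")
  has_uBC <- kind %in% c("PED", "GEN", "GEN_UNI_CB")
  if (has_uAA) add_block("uAA", ids_A)
  if (has_uAC) add_block("uAC", ids_A)
  if (has_uBC) add_block("uBC", ids_B)

  layout <- data.frame(effect = eff, level = lev,
                       index = seq_along(eff), stringsAsFactors = FALSE)
  neq <- nrow(layout)
  eqi <- function(effect, level) {
    i <- layout$index[layout$effect == effect][
      match(level, layout$level[layout$effect == effect])]
    if (anyNA(i)) stop_tc("layout lookup failed for ", effect, ":",
                          paste(level[is.na(i)], collapse = ","))
    i
  }

  # --- incidence rows --------------------------------------------------
  build_M <- function(dat, fx, tag, pen_lev) {
    nr <- nrow(dat)
    if (!nr) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(0L, neq)))
    ii <- jj <- integer(0); xx <- numeric(0)
    put <- function(i, j, x) {
      ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
    }
    fixed_tag <- paste0("fixed", tag)
    put(seq_len(nr), rep(eqi(fixed_tag, "(Intercept)"), nr), rep(1, nr))
    for (f in rec$factors) {
      ls <- fx$factor_levels[[f]]
      if (length(ls) <= 1) next
      v <- as.character(dat[[f]])
      w <- which(v != ls[1])
      if (length(w)) {
        put(w, eqi(fixed_tag, paste0(f, "=", v[w])), rep(1, length(w)))
      }
    }
    for (cv in rec$covariates) {
      put(seq_len(nr), rep(eqi(fixed_tag, paste0("cov:", cv)), nr),
          dat[[cv]] - fx$centers[[cv]])
    }
    if (length(pen_lev)) {
      put(seq_len(nr), eqi(paste0("pen", tag), as.character(dat$pen)),
          rep(1, nr))
    }
    if (tag == "A") {
      put(seq_len(nr), eqi("uAA", dat$animal), rep(1, nr))
    } else {
      put(seq_len(nr), eqi("uAC", dat$sire), rep(1, nr))
      put(seq_len(nr), eqi("uBC", dat$dam), rep(1, nr))
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, neq))
  }
  M_A <- build_M(dat_A, fxA, "A", penA_lev)
  M_C <- build_M(dat_C, fxC, "C", penC_lev)

  structure(list(
    M_A = M_A, M_C = M_C,
    y_A = dat_A[[spec$trait]], y_C = dat_C[[spec$trait]],
    rec_A = dat_A, rec_C = dat_C,
    layout = layout, spec = spec,
    ids_A = ids_A, ids_B = ids_B,
    fxA = fxA, fxC = fxC,
    penA_lev = penA_lev, penC_lev = penC_lev,
    idx = list(
      uAA = if (has_uAA) eqi("uAA", ids_A) else integer(0),
      uAC = if (has_uAC) eqi("uAC", ids_A) else integer(0),
      uBC = if (has_uBC && length(ids_B)) eqi("uBC", ids_B) else integer(0),
      penA = if (length(penA_lev)) eqi("penA", penA_lev) else integer(0),
      penC = if (length(penC_lev)) eqi("penC", penC_lev) else integer(0))
  ), class = "tc_design")
}

#' @export
print.tc_design <- function(x, ...) {
  cat(sprintf("<tc_design> %s/%s: %d PB + %d CB records, %d equations\n",
              x$spec$kind, x$spec$trait, nrow(x$M_A), nrow(x$M_C),
              nrow(x$layout)))
  invisible(x)
}

#' Select candidates for selection among purebred offspring
#'
#' Per sire: one candidate if the sire has fewer than four purebred
#' offspring with records, two otherwise; picked deterministically in
#' lexicographic id order (or uniformly at random when `seed` is given).
#'
#' @param ped sire-line pedigree (unused beyond documentation of scope;
#'   candidates are drawn from the trait table's PB records).
#' @param data trait table.
#' @param seed optional integer; if given, candidates are sampled.
#' @return Character vector of candidate ids.
#' @export
select_candidates <- function(ped, data, seed = NULL) {
  pb <- data[data$breed_type == "PB", , drop = FALSE]
  out <- character(0)
  for (s in sort(unique(pb$sire))) {
    offs <- sort(unique(pb$animal[pb$sire == s]))
    k <- if (length(offs) < 4) 1L else 2L
    k <- min(k, length(offs))
    pick <- if (is.null(seed)) offs[seq_len(k)] else {
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(as.integer(seed) + nchar(s))
      sample(offs, k)
    }
    out <- c(out, pick)
  }
  out
}

#' Mask phenotypes of selected animals
#'
#' Removes the records of `ids` from the likelihood; the animals remain in
#' the pedigree (and genotype panel), so they are still evaluated through
#' relatives.
#'
#' @param data trait table.
#' @param ids animal ids whose records are dropped.
#' @return The reduced trait table.
#' @export
mask_phenotypes <- function(data, ids) {
  if (!length(ids)) return(data)
  data[!(data$animal %in% ids), , drop = FALSE]
}

#' Read / write trait tables
#'
#' Tab-separated text with named columns; `NA` marks missing values.
#'
#' @param path file path.
#' @return data.frame (reader); `path` invisibly (writer).
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop_tc("phenotype file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  for (cc in intersect(c("animal", "sire", "dam", "batch", "pen",
                         "slaughter_date", "breed_type"), names(df))) {
    df[[cc]] <- as.character(df[[cc]])
  }
  df
}

#' @rdname read_trait_table
#' @param data trait table.
#' @export
write_trait_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
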