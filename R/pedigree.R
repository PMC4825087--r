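# Pedigree ingestion, topological ordering, inbreeding and numerator
# relationship matrices (A, A^-1) for a single breed line.

#' Construct a pedigree object
#'
#' A pedigree is a set of (animal, sire, dam) triples for one breed line.
#' Unknown parents are stored as `NA`. Animal ids must be unique and no
#' animal may be its own parent.
#'
#' @param id character vector of animal ids.
#' @param sire,dam character vectors of parent ids; `NA` for unknown.
#' @param line optional line label, e.g. `"sire_line"` or `"dam_line"`.
#' @return An object of class `tc_pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` and attributes `line` and `sorted`.
#' @export
tc_pedigree <- function(id, sire, dam, line = "sire_line") {
  id   <- as.character(id)
  sire <- as.character(sire)
  dam  <- as.character(dam)
  if (anyDuplicated(id)) {
    stop_tc("duplicate animal id(s): ",
            paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self)) {
    stop_tc("animal is its own parent: ", id[self[1]])
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  class(ped) <- c("tc_pedigree", "data.frame")
  attr(ped, "line") <- line
  attr(ped, "sorted") <- .ped_is_sorted(ped)
  ped
}

#' @export
print.tc_pedigree <- function(x, ...) {
  cat(sprintf("<tc_pedigree> %d animals, line = %s, sorted = %s\n",
              nrow(x), attr(x, "line"), attr(x, "sorted")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

.ped_is_sorted <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  ps <- pos[ped$sire]
  pd <- pos[ped$dam]
  all(is.na(ps) | ps < pos) && all(is.na(pd) | pd < pos)
}

# Integer-coded view: sire/dam indices with 0 = unknown (pedigree order).
.ped_codes <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  s <- idx[ped$sire]
  d <- idx[ped$dam]
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(s = unname(as.integer(s)), d = unname(as.integer(d)), n = nrow(ped))
}

.assert_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted"))) {
    stop_tc("pedigree must be topologically sorted ",
            "(call sort_and_truncate() first)")
  }
}

#' Read a pedigree file
#'
#' Reads delimited text with three id columns (animal, sire, dam). The
#' delimiter (comma, tab or whitespace) is auto-detected and an optional
#' header line is recognised. Parent entries equal to `unknown_code`
#' become unknown. Rows are returned verbatim; ordering is deferred to
#' [sort_and_truncate()].
#'
#' @param path file path.
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @param line line label passed to [tc_pedigree()].
#' @return A [tc_pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_code = "0", line = "sire_line") {
  if (!file.exists(path)) stop_tc("pedigree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop_tc("pedigree file is empty: ", path)
  sep <- if (grepl(",", lines[keep[1]], fixed = TRUE)) "," else
         if (grepl("\t", lines[keep[1]], fixed = TRUE)) "\t" else "[[:space:]]+"
  split1 <- function(x) {
    f <- strsplit(trimws(x), sep)[[1]]
    f[nzchar(f)]
  }
  first <- tolower(split1(lines[keep[1]]))
  header_words <- c("animal", "id", "sire", "dam", "father", "mother")
  if (any(first %in% header_words)) keep <- keep[-1]
  if (!length(keep)) stop_tc("pedigree file has a header but no rows: ", path)
  rows <- lapply(keep, function(k) {
    f <- split1(lines[k])
    if (length(f) < 3) {
      stop_tc("malformed pedigree row at line ", k, " of ", path,
              " (need 3 id columns, got ", length(f), ")")
    }
    f[1:3]
  })
  m <- do.call(rbind, rows)
  sire <- m[, 2]
  dam  <- m[, 3]
  sire[sire == unknown_code] <- NA_character_
  dam[dam == unknown_code]   <- NA_character_
  tc_pedigree(m[, 1], sire, dam, line = line)
}

#' Write a pedigree file
#'
#' Companion writer for [read_pedigree()]: comma-separated `animal,sire,dam`
#' with a header, unknown parents written as `unknown_code`.
#'
#' @param ped a [tc_pedigree()].
#' @param path output file path.
#' @param unknown_code token for unknown parents.
#' @export
write_pedigree <- function(ped, path, unknown_code = "0") {
  out <- data.frame(animal = ped$id,
                    sire = ifelse(is.na(ped$sire), unknown_code, ped$sire),
                    dam  = ifelse(is.na(ped$dam), unknown_code, ped$dam))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sort a pedigree topologically and truncate it at a generation horizon
#'
#' Retains the anchors and their ancestors up to `max_generations` meioses
#' back. A parent exactly at the horizon is kept but its own parents are
#' set to unknown. The result is ordered so that every known parent
#' precedes its offspring; ties are broken by input order, which makes the
#' operation deterministic and idempotent.
#'
#' @param ped a [tc_pedigree()].
#' @param anchors ids whose ancestry is kept (default: all animals).
#' @param max_generations meiosis-count horizon (default `Inf`).
#' @return A sorted, truncated [tc_pedigree()].
#' @export
sort_and_truncate <- function(ped, anchors = ped$id, max_generations = Inf) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  if (!all(anchors %in% ped$id)) {
    stop_tc("anchor id(s) not in pedigree: ",
            paste(setdiff(anchors, ped$id), collapse = ", "))
  }
  s <- idx[ped$sire]; s[is.na(s)] <- 0L
  d <- idx[ped$dam];  d[is.na(d)] <- 0L
  s <- as.integer(s); d <- as.integer(d)

  # BFS upward from the anchors, counting meioses.
  dist <- rep(Inf, n)
  queue <- unname(idx[anchors])
  dist[queue] <- 0
  while (length(queue)) {
    nxt <- integer(0)
    for (a in queue) {
      for (p in c(s[a], d[a])) {
        if (p > 0L && dist[a] + 1 < dist[p] && dist[a] + 1 <= max_generations) {
          dist[p] <- dist[a] + 1
          nxt <- c(nxt, p)
        }
      }
    }
    queue <- unique(nxt)
  }
  keep <- which(is.finite(dist))
  kept <- logical(n)
  kept[keep] <- TRUE
  # Parents beyond the horizon (or outside the kept ancestor set) -> unknown.
  s2 <- ifelse(s > 0L & kept[pmax(s, 1L)] & dist[pmax(s, 1L)] <= max_generations,
               s, 0L)
  d2 <- ifelse(d > 0L & kept[pmax(d, 1L)] & dist[pmax(d, 1L)] <= max_generations,
               d, 0L)
  s2[!kept] <- 0L; d2[!kept] <- 0L

  # Kahn topological sort over the kept set, ties by input position.
  indeg <- integer(n)
  for (a in keep) {
    for (p in c(s2[a], d2[a])) if (p > 0L) indeg[a] <- indeg[a] + 1L
  }
  children <- split(rep(keep, 2L), c(s2[keep], d2[keep]))
  children[["0"]] <- NULL
  ready <- sort(keep[indeg[keep] == 0L])
  out <- integer(0)
  while (length(ready)) {
    a <- ready[1]
    ready <- ready[-1]
    out <- c(out, a)
    for (ch in children[[as.character(a)]] %||% integer(0)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(out) < length(keep)) {
    cyc <- setdiff(keep, out)
    stop_tc("pedigree contains a cycle involving animal: ", ped$id[cyc[1]])
  }
  res <- tc_pedigree(
    ped$id[out],
    ifelse(s2[out] > 0L, ped$id[pmax(s2[out], 1L)], NA_character_),
    ifelse(d2[out] > 0L, ped$id[pmax(d2[out], 1L)], NA_character_),
    line = attr(ped, "line")
  )
  attr(res, "sorted") <- TRUE
  res
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients F on a sorted pedigree with
#' the recursive algorithm of Meuwissen and Luo (1992). Unknown parents are
#' treated as unrelated, non-inbred base animals, so F = 0 whenever either
#' parent is unknown. `F` equals `diag(build_A(ped)) - 1`.
#'
#' @param ped a sorted [tc_pedigree()].
#' @return Named numeric vector of inbreeding coefficients in `[0, 1)`.
#' @export
compute_inbreeding <- function(ped) {
  .assert_sorted(ped)
  pc <- .ped_codes(ped)
  s <- pc$s; d <- pc$d; n <- pc$n
  F <- numeric(n)
  if (n == 0L) return(setNames(F, character(0)))
  # Mendelian sampling variance of animal j given parental inbreeding;
  # unknown parents contribute F = -1 in the usual bookkeeping.
  Fpar <- function(p) if (p == 0L) -1 else F[p]
  L <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    if (i > 1L && s[i] == s[i - 1L] && d[i] == d[i - 1L]) {
      F[i] <- F[i - 1L]  # full sibs share F
      next
    }
    # a_ii = sum over ancestors j of L_j^2 * D_j ; F_i = a_ii - 1.
    aii <- 0
    L[i] <- 1
    anc <- i
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      if (s[j] > 0L) { L[s[j]] <- L[s[j]] + 0.5 * L[j]; anc <- union(anc, s[j]) }
      if (d[j] > 0L) { L[d[j]] <- L[d[j]] + 0.5 * L[j]; anc <- union(anc, d[j]) }
      Dj <- 0.5 - 0.25 * (Fpar(s[j]) + Fpar(d[j]))
      aii <- aii + L[j]^2 * Dj
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  setNames(F, ped$id)
}

#' Numerator relationship matrix by the tabular method
#'
#' Runs the tabular recursion over the whole sorted pedigree, then restricts
#' rows/columns to `subset` (e.g. the genotyped set, giving the A22 block).
#'
#' @param ped a sorted [tc_pedigree()].
#' @param subset ids to retain (default: all animals).
#' @return Dense symmetric matrix with dimnames = ids, diagonal `1 + F`.
#' @export
build_A <- function(ped, subset = NULL) {
  .assert_sorted(ped)
  pc <- .ped_codes(ped)
  s <- pc$s; d <- pc$d; n <- pc$n
  if (!is.null(subset) && !all(subset %in% ped$id)) {
    stop_tc("subset id(s) not in pedigree: ",
            paste(setdiff(subset, ped$id), collapse = ", "))
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (si > 0L) A[j, si] else 0
      ad_ <- if (di > 0L) A[j, di] else 0
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + (if (si > 0L && di > 0L) 0.5 * A[si, di] else 0)
  }
  dimnames(A) <- list(ped$id, ped$id)
  if (!is.null(subset)) A <- A[subset, subset, drop = FALSE]
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' For the full pedigree, applies Henderson's rules with inbreeding
#' (Mendelian-sampling variances computed from parental F). For a proper
#' subset of animals, densely inverts `build_A(ped, subset)` (the inverse of
#' a submatrix is not sparse in general). In both cases the product with
#' the corresponding relationship matrix is the identity to 1e-8.
#'
#' @param ped a sorted [tc_pedigree()].
#' @param subset ids of a proper subset, or `NULL` for the whole pedigree.
#' @return A symmetric sparse [Matrix::Matrix] with dimnames = ids.
#' @export
build_A_inverse <- function(ped, subset = NULL) {
  .assert_sorted(ped)
  if (!is.null(subset) && !setequal(subset, ped$id)) {
    if (!all(subset %in% ped$id)) {
      stop_tc("subset id(s) not in pedigree: ",
              paste(setdiff(subset, ped$id), collapse = ", "))
    }
    Asub <- build_A(ped, subset)
    if (rcond(Asub) < 1e-12) {
      stop_tc("restricted relationship matrix is numerically singular")
    }
    Ainv <- solve(Asub)
    Ainv <- (Ainv + t(Ainv)) / 2
    return(methods::as(methods::as(Matrix::Matrix(Ainv, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix"))
  }
  pc <- .ped_codes(ped)
  s <- pc$s; d <- pc$d; n <- pc$n
  F <- unname(compute_inbreeding(ped))
  Fg <- function(p) ifelse(p == 0L, -1, F[pmax(p, 1L)])
  Dvec <- 0.5 - 0.25 * (Fg(s) + Fg(d))
  alpha <- 1 / Dvec
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  for (p in list(s, d)) {
    w <- which(p > 0L)
    add(w, p[w], -alpha[w] / 2)
    add(p[w], w, -alpha[w] / 2)
  }
  ws <- which(s > 0L & d > 0L)
  add(s[ws], s[ws], alpha[ws] / 4)
  add(d[ws], d[ws], alpha[ws] / 4)
  add(s[ws], d[ws], alpha[ws] / 4)
  add(d[ws], s[ws], alpha[ws] / 4)
  wso <- which(s > 0L & d == 0L)
  add(s[wso], s[wso], alpha[wso] / 4)
  wdo <- which(d > 0L & s == 0L)
  add(d[wdo], d[wdo], alpha[wdo] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Ainv, "CsparseMatrix")
}

#' Write / read a symmetric matrix in coordinate text format
#'
#' One `i j value` line per upper-triangle nonzero (1-based), plus a
#' sidecar file `<path>.ids` holding the id index, one id per line.
#'
#' @param m matrix (dense or sparse) with dimnames.
#' @param path output path.
#' @return `path`, invisibly (writer); the matrix as a symmetric sparse
#'   Matrix (reader).
#' @export
write_coord_matrix <- function(m, path) {
  ids <- rownames(m)
  M <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  keep <- M@i <= M@j  # upper triangle incl. diagonal
  df <- data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L, x = M@x[keep])
  df <- df[df$x != 0, ]
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(ids, paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_coord_matrix
#' @export
read_coord_matrix <- function(path) {
  ids <- readLines(paste0(path, ".ids"))
  df <- utils::read.table(path, col.names = c("i", "j", "x"))
  n <- length(ids)
  up <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x, dims = c(n, n),
                             dimnames = list(ids, ids))
  lo <- Matrix::t(up)
  Matrix::diag(lo) <- 0
  methods::as(up + lo, "CsparseMatrix")
}
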