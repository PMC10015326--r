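#' Construct and validate a pedigree table
#'
#' A pedigree table records, for every individual, its sire and dam (or
#' unknown, coded `NA`, `""` or `"0"`), its generation index, sex, and a
#' mating-arm label (`"parent"`, `"outbred"` or `"inbred"`).  Validation
#' checks id uniqueness, detects cycles, promotes parents that are absent
#' from the records to founders (with a warning), and returns the table
#' sorted so that parents precede their offspring.
#'
#' @param df A `data.frame` with columns `id`, `sire`, `dam`, and
#'   optionally `sex`, `generation`, `arm`.
#' @return A validated `pedigree_table` (a `data.frame` in topological
#'   order, with attribute `validated = TRUE`).
#' @examples
#' ped <- pedigree_table(data.frame(
#'   id = c("o1", "f1", "f2"), sire = c("f1", NA, NA),
#'   dam = c("f2", NA, NA)))
#' ped$id  # founders first
#' @export
pedigree_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree must have columns id, sire, dam")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$sire <- normalize_parent(df$sire)
  df$dam <- normalize_parent(df$dam)
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  if (!"generation" %in% names(df)) df$generation <- NA_integer_
  if (!"arm" %in% names(df)) df$arm <- "parent"
  validate_pedigree(df)
}

# unknown-parent dialects: NA, "", "0" all mean unknown
normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

#' Validate a raw pedigree table
#'
#' Checks structural invariants (unique ids, no individual its own
#' ancestor, parents known or explicitly promoted to founders) and
#' topologically sorts the records parent-before-offspring.  Usually
#' called via [pedigree_table()].
#'
#' @param df A `data.frame` with columns `id`, `sire`, `dam` (parent
#'   columns already normalized: `NA` = unknown).
#' @return The sorted, validated `pedigree_table`.
#' @export
validate_pedigree <- function(df) {
  if (anyDuplicated(df$id))
    stop("duplicate pedigree ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!is.na(df$sire) & df$sire == df$id) ||
      any(!is.na(df$dam) & df$dam == df$id))
    stop("pedigree cycle: individual listed as its own parent: ",
         paste(df$id[(!is.na(df$sire) & df$sire == df$id) |
                     (!is.na(df$dam) & df$dam == df$id)], collapse = ", "))
  # promote parents missing from the records to founders
  known <- df$id
  missing_par <- setdiff(c(df$sire, df$dam), c(known, NA_character_))
  if (length(missing_par)) {
    warning("parent id(s) absent from records promoted to founders: ",
            paste(missing_par, collapse = ", "))
    add <- df[rep(1L, length(missing_par)), , drop = FALSE]
    add$id <- missing_par
    add$sire <- NA_character_
    add$dam <- NA_character_
    add$sex <- NA_character_
    add$generation <- if (is.numeric(df$generation) &&
                          any(!is.na(df$generation)))
      min(df$generation, na.rm = TRUE) - 1L else NA_integer_
    add$arm <- "parent"
    df <- rbind(add, df)
    rownames(df) <- NULL
  }
  ord <- topo_order(df$id, df$sire, df$dam)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validated") <- TRUE
  class(out) <- c("pedigree_table", "data.frame")
  out
}

# Kahn's algorithm; errors on cycles naming the individuals involved.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n)
    stop("pedigree cycle involving: ",
         paste(id[setdiff(idx, out)], collapse = ", "))
  out
}

stopifnot_validated <- function(ped) {
  if (!inherits(ped, "pedigree_table") || !isTRUE(attr(ped, "validated")))
    stop("pedigree must be validated; use pedigree_table() first")
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix **A** with the
#' classic tabular recursion: processing individuals in topological
#' order, `A[i, j] = (A[j, sire_i] + A[j, dam_i]) / 2` for earlier `j`,
#' and `A[i, i] = 1 + A[sire_i, dam_i] / 2`; unknown parents contribute
#' zero.  Diagonals therefore equal `1 + F`, which is how the animal
#' model absorbs the purely additive `(1 + F)` inflation of genetic
#' variance under inbreeding.
#'
#' @param ped A validated [pedigree_table()].
#' @return A `relationship_matrix`: dense symmetric matrix with dimnames
#'   equal to the individual ids.
#' @examples
#' ped <- pedigree_table(data.frame(id = c("f1", "f2", "o"),
#'   sire = c(NA, NA, "f1"), dam = c(NA, NA, "f2")))
#' build_A(ped)["f1", "o"]  # 0.5
#' @export
build_A <- function(ped) {
  stopifnot_validated(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in idx) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  structure(A, class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> ", nrow(x), " individuals; mean F = ",
      format(mean(diag(x)) - 1, digits = 4), "\n", sep = "")
  if (nrow(x) <= 12L) print(unclass(x), ...) else utils::str(unclass(x))
  invisible(x)
}

#' Export a relationship matrix as sparse triplets
#'
#' @param A A `relationship_matrix` from [build_A()].
#' @param tol Entries with absolute value below `tol` are dropped.
#' @return A `Matrix::dsTMatrix` (symmetric sparse triplet form).
#' @export
sparse_A <- function(A, tol = 0) {
  stopifnot(inherits(A, "relationship_matrix"))
  M <- unclass(A)
  M[abs(M) <= tol & row(M) != col(M)] <- 0
  methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE), "symmetricMatrix"),
              "TsparseMatrix")
}

#' Pedigree inbreeding coefficients
#'
#' `F_i` is half the additive relationship between the parents of `i`
#' (zero for founders and individuals with an unknown parent); it equals
#' the diagonal of **A** minus one, exactly.
#'
#' @param ped A validated [pedigree_table()].
#' @param A Optionally, a precomputed [build_A()] result for `ped`.
#' @return Named numeric vector of inbreeding coefficients.
#' @examples
#' ped <- mcn_example_pedigree()
#' inbreeding_coefficients(ped)[["x"]]  # full-sib offspring: 0.25
#' @export
inbreeding_coefficients <- function(ped, A = NULL) {
  stopifnot_validated(ped)
  if (is.null(A)) A <- build_A(ped)
  F <- diag(unclass(A)) - 1
  names(F) <- ped$id
  F
}

#' Five-individual example pedigree
#'
#' Two unrelated founders, their two full-sib offspring, and one
#' offspring (`"x"`) of those full sibs, whose inbreeding coefficient is
#' 0.25 — the paired design's inbred arm in miniature.
#'
#' @return A validated `pedigree_table`.
#' @export
mcn_example_pedigree <- function() {
  pedigree_table(data.frame(
    id = c("f1", "f2", "s1", "s2", "x"),
    sire = c(NA, NA, "f1", "f1", "s1"),
    dam = c(NA, NA, "f2", "f2", "s2"),
    sex = c("M", "F", "M", "F", "M"),
    generation = c(0L, 0L, 1L, 1L, 2L),
    arm = c("parent", "parent", "parent", "parent", "inbred"),
    stringsAsFactors = FALSE))
}

#' Read / write pedigree CSV
#'
#' The pedigree CSV dialect has header columns `id, sire, dam, sex,
#' generation, arm`; unknown parents are coded `"0"` or empty; UTF-8.
#'
#' @param path File path.
#' @return `read_pedigree_csv()` returns a validated `pedigree_table`.
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if ("generation" %in% names(df))
    df$generation <- as.integer(df$generation)
  pedigree_table(df)
}

#' @param ped A `pedigree_table` to write.
#' @rdname read_pedigree_csv
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
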