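## Inclusion-maximal all-ones bicluster mining of a binarized enrichment
## matrix.
##
## A bicluster (R, C) is maximal when no row or column can be added while
## keeping the submatrix all-ones. Maximal biclusters with a non-empty
## column set are exactly the "closed" pairs: C is an intersection of row
## supports and R is the full set of rows whose support contains C. The
## miner enumerates closed column sets by iterated intersection of row
## supports (a fixpoint that visits every intersection of supports), then
## reads off the extents; the brute-force oracle instead walks all row
## subsets directly.

biclusterKey <- function(rows, cols) {
  paste(paste(rows, collapse = ","), paste(cols, collapse = ","), sep = "|")
}

orderBiclusters <- function(bcs) {
  if (length(bcs) == 0L) return(bcs)
  keys <- vapply(bcs, function(b) {
    paste(paste(sprintf("%06d", b$rows), collapse = ","),
          paste(sprintf("%06d", b$cols), collapse = ","), sep = "|")
  }, character(1))
  bcs[order(keys)]
}

checkBinary <- function(binary) {
  stopifnot2(is.matrix(binary), "input must be a matrix")
  if (!all(binary %in% c(0, 1))) {
    stop("matrix entries must be 0 or 1; binarize scores first", call. = FALSE)
  }
}

#' Mine all inclusion-maximal all-ones biclusters
#'
#' Enumerates every maximal all-ones submatrix (set of rows x set of
#' columns) of a binary matrix that meets the size minima. The default
#' minima of 2 x 2 suppress single-term / single-matrix trivia. Output is
#' deduplicated and deterministically ordered (lexicographically by row set
#' then column set).
#'
#' @param binary 0/1 matrix (e.g. from [binarizeMatrix()]).
#' @param minRows,minCols Minimum bicluster dimensions (>= 1).
#' @return List of biclusters, each a list with sorted integer vectors
#'   `rows` and `cols` (and `row_names`/`col_names` when the matrix has
#'   dimnames).
#' @seealso [bruteForceBiclusters()] for the enumeration oracle.
#' @examples
#' m <- matrix(1, 4, 3)
#' bimaxBiclusters(m, 2, 2)  # the whole matrix
#' @export
bimaxBiclusters <- function(binary, minRows = 2, minCols = 2) {
  checkBinary(binary)
  stopifnot2(minRows >= 1 && minCols >= 1, "size minima must be >= 1")
  n <- nrow(binary)
  supp <- lapply(seq_len(n), function(i) which(binary[i, ] == 1))
  base <- unique(supp[lengths(supp) > 0L])
  seen <- new.env(parent = emptyenv())
  keyOf <- function(c) paste(c, collapse = ",")
  for (s in base) assign(keyOf(s), s, envir = seen)
  frontier <- base
  while (length(frontier) > 0L) {
    fresh <- list()
    for (a in frontier) {
      for (s in base) {
        i <- intersect(a, s)
        if (length(i) == 0L) next
        k <- keyOf(i)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, i, envir = seen)
          fresh[[length(fresh) + 1L]] <- i
        }
      }
    }
    frontier <- fresh
  }
  intents <- mget(ls(seen), envir = seen)
  out <- list()
  for (C in intents) {
    if (length(C) < minCols) next
    R <- which(vapply(supp, function(s) all(C %in% s), logical(1)))
    if (length(R) < minRows) next
    out[[length(out) + 1L]] <- newBicluster(R, sort(C), binary)
  }
  orderBiclusters(out)
}

newBicluster <- function(rows, cols, binary) {
  b <- list(rows = as.integer(rows), cols = as.integer(cols))
  if (!is.null(rownames(binary))) b$row_names <- rownames(binary)[b$rows]
  if (!is.null(colnames(binary))) b$col_names <- colnames(binary)[b$cols]
  b
}

#' Brute-force bicluster enumeration oracle
#'
#' Walks all 2^nrow row subsets, takes each subset's common all-ones
#' columns, and keeps the inclusion-maximal results meeting the minima.
#' Refuses matrices with more than 14 rows.
#'
#' @inheritParams bimaxBiclusters
#' @return List of biclusters in the same form and order as
#'   [bimaxBiclusters()].
#' @export
bruteForceBiclusters <- function(binary, minRows = 2, minCols = 2) {
  checkBinary(binary)
  n <- nrow(binary)
  stopifnot2(n <= 14L, "brute-force enumeration limited to 14 rows")
  supp <- lapply(seq_len(n), function(i) which(binary[i, ] == 1))
  cand <- new.env(parent = emptyenv())
  for (mask in seq_len(2^n - 1L)) {
    R0 <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    C <- Reduce(intersect, supp[R0])
    if (length(C) == 0L) next
    k <- paste(C, collapse = ",")
    prev <- if (exists(k, envir = cand, inherits = FALSE)) get(k, envir = cand) else integer(0)
    assign(k, union(prev, R0), envir = cand)
  }
  keys <- ls(cand)
  pairs <- lapply(keys, function(k) {
    list(rows = sort(get(k, envir = cand)),
         cols = as.integer(strsplit(k, ",", fixed = TRUE)[[1L]]))
  })
  ## drop non-maximal pairs (row set contained in another with superset cols)
  keep <- rep(TRUE, length(pairs))
  for (i in seq_along(pairs)) {
    for (j in seq_along(pairs)) {
      if (i == j) next
      if (all(pairs[[i]]$rows %in% pairs[[j]]$rows) &&
          all(pairs[[i]]$cols %in% pairs[[j]]$cols)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pairs <- pairs[keep]
  pairs <- Filter(function(b) length(b$rows) >= minRows && length(b$cols) >= minCols,
                  pairs)
  orderBiclusters(lapply(pairs, function(b) newBicluster(b$rows, sort(b$cols), binary)))
}

#' Export biclusters as text
#'
#' One line per bicluster: semicolon-separated term (row) names, a tab,
#' then semicolon-separated matrix (column) names. Falls back to indices
#' when the matrix had no dimnames.
#'
#' @param biclusters List from [bimaxBiclusters()].
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
writeBiclusters <- function(biclusters, file) {
  lines <- vapply(biclusters, function(b) {
    r <- if (!is.null(b$row_names)) b$row_names else b$rows
    c <- if (!is.null(b$col_names)) b$col_names else b$cols
    paste(paste(r, collapse = ";"), paste(c, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
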