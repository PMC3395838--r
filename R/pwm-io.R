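## Matrix-collection I/O for the four supported dialects.
##
## TRANSFAC: "ID <acc>" / optional "NA <names>" / "P0 A C G T" header /
##   numbered position rows / "//" record terminator.
## JASPAR:   ">id names" followed by four letter rows "A [ 1 2 3 ]".
## UNIPROBE: "id names" header followed by "A: ..." ... "T: ..." rows,
##   records separated by blank lines.
## generic:  ">id names" followed by W rows of 4 numbers (A C G T).
##
## A record whose position sums are all ~1 is treated as a probability
## matrix: it is renormalized per position, and smoothed with the
## pseudocount rule only when it contains zeros (so writing a collection
## and reading it back is an identity). Anything else is treated as counts
## and regularized with countsToProbabilities().

#' Read a PWM collection
#'
#' Parses TRANSFAC, JASPAR, UNIPROBE or generic tabular matrix files into
#' [PositionWeightMatrix-class] objects. Count matrices are regularized via
#' [countsToProbabilities()]; matrices already expressed as probabilities
#' are renormalized (and floored with the pseudocount rule only if they
#' contain zeros, so that round trips are exact). Record order is
#' preserved.
#'
#' @param file Path to a matrix file, or a character vector of lines.
#' @param dialect One of `"auto"`, `"transfac"`, `"jaspar"`, `"uniprobe"`,
#'   `"generic"`.
#' @param pseudocount Pseudocount passed to [countsToProbabilities()].
#' @param background Background used to distribute the pseudocount.
#' @return List of [PositionWeightMatrix-class] objects.
#' @seealso [writePwmCollection()]
#' @export
readPwmCollection <- function(file, dialect = "auto", pseudocount = 1,
                              background = uniformBackground()) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file)
  } else if (length(file) == 1L && grepl("\n", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(file)
  }
  if (identical(dialect, "auto")) dialect <- detectPwmDialect(lines)
  parser <- switch(dialect,
    transfac = parseTransfac,
    jaspar = parseJaspar,
    uniprobe = parseUniprobe,
    generic = parseGenericPwm,
    stop(sprintf("unknown PWM dialect '%s'", dialect), call. = FALSE)
  )
  raw <- parser(lines)
  lapply(raw, function(rec) {
    regularizeRecord(rec, dialect, pseudocount, background)
  })
}

detectPwmDialect <- function(lines) {
  nb <- lines[nzchar(trimws(lines))]
  if (length(nb) == 0L) return("jaspar")  # empty stream: any parser yields list()
  if (grepl("^(ID|VV|AC)\\b", nb[1L])) return("transfac")
  if (any(grepl("^[ACGT]:", nb))) return("uniprobe")
  if (startsWith(nb[1L], ">")) {
    nxt <- nb[2L]
    if (!is.na(nxt) && grepl("^[ACGTacgt]\\s*[\\[0-9]", nxt)) return("jaspar")
    return("generic")
  }
  stop("cannot auto-detect PWM dialect; pass dialect= explicitly", call. = FALSE)
}

regularizeRecord <- function(rec, dialect, pseudocount, background) {
  m <- rec$mat  # W x 4, A C G T
  sums <- rowSums(m)
  isProb <- all(abs(sums - 1) < 1e-3)
  if (isProb) {
    p <- m / sums
    if (any(p <= 0)) {
      bg <- bgProbs(background)
      p <- sweep(p, 2, bg * pseudocount, "+") / (1 + pseudocount)
    }
    probs <- t(p)
    rownames(probs) <- NUC
  } else {
    ## transpose explicitly: a 4 x 4 record is ambiguous to the helper
    probs <- countsToProbabilities(t(m), pseudocount = pseudocount,
                                   background = background)
  }
  newPwm(rec$id, probs, factorNames = rec$names, dialect = dialect)
}

pwmParseError <- function(recordIndex, line, why) {
  stop(sprintf("malformed PWM record %d near line '%s': %s",
               recordIndex, substr(line, 1, 60), why), call. = FALSE)
}

splitNames <- function(x) {
  out <- unlist(strsplit(trimws(x), "[;[:space:]]+"))
  out[nzchar(out)]
}

parseTransfac <- function(lines) {
  recs <- list()
  cur <- NULL
  idx <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) pwmParseError(idx, "//", "record without ID line")
    if (length(cur$rows) == 0L) pwmParseError(idx, cur$id, "record without position rows")
    recs[[length(recs) + 1L]] <<- list(
      id = cur$id, names = cur$names,
      mat = do.call(rbind, cur$rows))
    cur <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (startsWith(t, "//")) { flush(); next }
    tok <- strsplit(t, "\\s+")[[1L]]
    tag <- tok[1L]
    if (tag == "ID") {
      if (!is.null(cur)) flush()
      idx <- idx + 1L
      if (length(tok) < 2L) pwmParseError(idx, ln, "ID line without identifier")
      cur <- list(id = tok[2L], names = character(0), rows = list())
    } else if (is.null(cur)) {
      if (tag %in% c("AC", "VV", "XX")) next
      pwmParseError(idx + 1L, ln, "content before ID line")
    } else if (tag == "NA" || tag == "BF") {
      cur$names <- c(cur$names, splitNames(paste(tok[-1L], collapse = " ")))
    } else if (grepl("^P[0O]$", tag)) {
      if (!identical(toupper(tok[2:5]), NUC)) {
        pwmParseError(idx, ln, "P0 header must list A C G T")
      }
    } else if (grepl("^[0-9]+$", tag)) {
      vals <- suppressWarnings(as.numeric(tok[2:5]))
      if (length(tok) < 5L || anyNA(vals)) {
        pwmParseError(idx, ln, "position row must carry 4 numeric values")
      }
      cur$rows[[length(cur$rows) + 1L]] <- vals
    } else if (tag %in% c("XX", "CC", "DE", "AC")) {
      next
    } else {
      pwmParseError(idx, ln, "unrecognized line tag")
    }
  }
  flush()
  recs
}

parseJaspar <- function(lines) {
  recs <- list()
  cur <- NULL
  idx <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    miss <- setdiff(NUC, names(cur$rows))
    if (length(miss)) pwmParseError(idx, cur$id, paste("missing rows:", paste(miss, collapse = ",")))
    lens <- lengths(cur$rows[NUC])
    if (length(unique(lens)) != 1L) pwmParseError(idx, cur$id, "letter rows of unequal length")
    recs[[length(recs) + 1L]] <<- list(
      id = cur$id, names = cur$names,
      mat = cbind(A = cur$rows$A, C = cur$rows$C, G = cur$rows$G, T = cur$rows$T))
    cur <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (startsWith(t, ">")) {
      flush()
      idx <- idx + 1L
      hdr <- splitNames(sub("^>", "", t))
      if (length(hdr) == 0L) pwmParseError(idx, ln, "empty header")
      cur <- list(id = hdr[1L], names = hdr[-1L], rows = list())
    } else if (is.null(cur)) {
      pwmParseError(idx + 1L, ln, "matrix row before '>' header")
    } else {
      letter <- toupper(substr(t, 1L, 1L))
      if (!letter %in% NUC) pwmParseError(idx, ln, "row must start with A/C/G/T")
      body <- gsub("\\[|\\]", " ", substr(t, 2L, nchar(t)))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1L]]))
      if (length(vals) == 0L || anyNA(vals)) pwmParseError(idx, ln, "non-numeric matrix row")
      cur$rows[[letter]] <- vals
    }
  }
  flush()
  recs
}

parseUniprobe <- function(lines) {
  recs <- list()
  cur <- NULL
  idx <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    miss <- setdiff(NUC, names(cur$rows))
    if (length(miss)) pwmParseError(idx, cur$id, paste("missing rows:", paste(miss, collapse = ",")))
    lens <- lengths(cur$rows[NUC])
    if (length(unique(lens)) != 1L) pwmParseError(idx, cur$id, "letter rows of unequal length")
    recs[[length(recs) + 1L]] <<- list(
      id = cur$id, names = cur$names,
      mat = cbind(A = cur$rows$A, C = cur$rows$C, G = cur$rows$G, T = cur$rows$T))
    cur <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) { flush(); next }
    if (grepl("^[ACGTacgt]:", t)) {
      if (is.null(cur)) pwmParseError(idx + 1L, ln, "matrix row before header line")
      letter <- toupper(substr(t, 1L, 1L))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(substr(t, 3L, nchar(t))), "[[:space:],]+")[[1L]]))
      if (length(vals) == 0L || anyNA(vals)) pwmParseError(idx, ln, "non-numeric matrix row")
      cur$rows[[letter]] <- vals
    } else {
      flush()
      idx <- idx + 1L
      hdr <- splitNames(t)
      cur <- list(id = hdr[1L], names = hdr[-1L], rows = list())
    }
  }
  flush()
  recs
}

parseGenericPwm <- function(lines) {
  recs <- list()
  cur <- NULL
  idx <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (length(cur$rows) == 0L) pwmParseError(idx, cur$id, "record without position rows")
    recs[[length(recs) + 1L]] <<- list(
      id = cur$id, names = cur$names, mat = do.call(rbind, cur$rows))
    cur <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t) || startsWith(t, "#")) next
    if (startsWith(t, ">")) {
      flush()
      idx <- idx + 1L
      hdr <- splitNames(sub("^>", "", t))
      if (length(hdr) == 0L) pwmParseError(idx, ln, "empty header")
      cur <- list(id = hdr[1L], names = hdr[-1L], rows = list())
    } else if (is.null(cur)) {
      pwmParseError(idx + 1L, ln, "matrix row before '>' header")
    } else {
      if (grepl("^[Aa]\\s", t)) next  # optional "A C G T" column header
      vals <- suppressWarnings(as.numeric(strsplit(t, "[[:space:],]+")[[1L]]))
      if (length(vals) != 4L || anyNA(vals)) {
        pwmParseError(idx, ln, "position row must carry exactly 4 numeric values")
      }
      cur$rows[[length(cur$rows) + 1L]] <- vals
    }
  }
  flush()
  recs
}

#' Write a PWM collection
#'
#' Serializes matrices (as probabilities) in the requested dialect. Reading
#' the output back with [readPwmCollection()] reproduces ids, names and
#' probabilities (within printed precision).
#'
#' @param pwms List of [PositionWeightMatrix-class] objects.
#' @param file Output path.
#' @param dialect One of `"transfac"`, `"jaspar"`, `"uniprobe"`,
#'   `"generic"`.
#' @return Invisibly, the path written.
#' @export
writePwmCollection <- function(pwms, file, dialect = "jaspar") {
  fmtRow <- function(v) paste(sprintf("%.12g", v), collapse = " ")
  out <- character(0)
  for (pwm in pwms) {
    p <- pwmProbs(pwm)
    nm <- paste(factorNames(pwm), collapse = ";")
    if (dialect == "jaspar") {
      out <- c(out, paste0(">", pwmId(pwm), if (nzchar(nm)) paste0(" ", nm)),
               vapply(NUC, function(n) sprintf("%s [ %s ]", n, fmtRow(p[n, ])),
                      character(1)))
    } else if (dialect == "transfac") {
      rows <- vapply(seq_len(ncol(p)), function(w) {
        sprintf("%02d %s", w, fmtRow(p[, w]))
      }, character(1))
      out <- c(out, paste("ID", pwmId(pwm)),
               if (nzchar(nm)) paste("NA", nm),
               "P0 A C G T", rows, "//")
    } else if (dialect == "uniprobe") {
      out <- c(out, paste(pwmId(pwm), nm),
               vapply(NUC, function(n) sprintf("%s: %s", n, fmtRow(p[n, ])),
                      character(1)),
               "")
    } else if (dialect == "generic") {
      out <- c(out, paste0(">", pwmId(pwm), if (nzchar(nm)) paste0(" ", nm)),
               vapply(seq_len(ncol(p)), function(w) fmtRow(p[, w]), character(1)))
    } else {
      stop(sprintf("unknown PWM dialect '%s'", dialect), call. = FALSE)
    }
  }
  writeLines(out, file)
  invisible(file)
}
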