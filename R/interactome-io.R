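## Flat-file input for the interaction-graph module.

INTERACTION_CATEGORIES <- c("tf_target_predicted", "tf_target_chip",
                            "tf_target_curated", "mirna_target",
                            "kinase_substrate", "ppi")
REGULATORY_CATEGORIES <- c("tf_target_predicted", "tf_target_chip",
                           "tf_target_curated", "mirna_target")
EDGE_SIGNS <- c("activation", "repression", "ambiguous", "none")

#' Load a tabulated interaction file
#'
#' Tab-separated with a header; columns `source`, `target`, `category` and
#' optionally `sign` and `provenance`. Typing and defaulting rules:
#' protein-protein (`ppi`) records are undirected and must carry no sign;
#' regulatory and kinase records are directed; `mirna_target` records
#' default to `repression` when the sign is unspecified; other regulatory
#' records default to `ambiguous`.
#'
#' @param file Path, or a character vector of lines.
#' @return data.frame of interaction records: `source_id`, `target_id`,
#'   `category`, `sign`, `directed`, `provenance`.
#' @export
readInteractionTable <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else as.character(file)
  lines <- lines[nzchar(trimws(lines))]
  stopifnot2(length(lines) >= 1L, "interaction file must at least carry a header")
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  stopifnot2(all(c("source", "target", "category") %in% hdr),
             "header must name columns source, target, category")
  body <- lines[-1L]
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < length(hdr)) tok <- c(tok, rep("", length(hdr) - length(tok)))
    if (length(tok) != length(hdr)) {
      stop(sprintf("line %d: expected %d fields, got %d", i + 1L, length(hdr),
                   length(tok)), call. = FALSE)
    }
    row <- setNames(as.list(tok), hdr)
    cat. <- row$category
    if (!cat. %in% INTERACTION_CATEGORIES) {
      stop(sprintf("line %d: unknown interaction category '%s'", i + 1L, cat.),
           call. = FALSE)
    }
    sign <- if (!is.null(row$sign)) trimws(row$sign) else ""
    if (cat. == "ppi") {
      if (nzchar(sign) && sign != "none") {
        stop(sprintf("line %d: ppi records are unsigned (got '%s')", i + 1L, sign),
             call. = FALSE)
      }
      sign <- "none"
    } else if (!nzchar(sign)) {
      sign <- if (cat. == "mirna_target") "repression" else "ambiguous"
    }
    if (!sign %in% EDGE_SIGNS) {
      stop(sprintf("line %d: unknown sign '%s'", i + 1L, sign), call. = FALSE)
    }
    recs[[i]] <- data.frame(
      source_id = row$source, target_id = row$target, category = cat.,
      sign = sign, directed = cat. != "ppi",
      provenance = if (!is.null(row$provenance)) row$provenance else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(recs, list(emptyInteractions())))
  rownames(out) <- NULL
  out
}

emptyInteractions <- function() {
  data.frame(source_id = character(0), target_id = character(0),
             category = character(0), sign = character(0),
             directed = logical(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

#' Write an interaction table
#'
#' Inverse of [readInteractionTable()].
#'
#' @param records Interaction data.frame.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
writeInteractionTable <- function(records, file) {
  df <- records[c("source_id", "target_id", "category", "sign", "provenance")]
  names(df) <- c("source", "target", "category", "sign", "provenance")
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' The bundled default compartment tree
#'
#' A pruned cellular-component hierarchy used as layout zones:
#' cell -> extracellular region, plasma membrane, intracellular ->
#' cytosol, nucleus, mitochondrion, endoplasmic reticulum, Golgi
#' apparatus. User trees can be supplied via [readCompartmentTree()].
#'
#' @return A [CompartmentTree-class].
#' @export
defaultCompartmentTree <- function() {
  nodes <- data.frame(
    term_id = c("cell", "extracellular region", "plasma membrane",
                "intracellular", "cytosol", "nucleus", "mitochondrion",
                "endoplasmic reticulum", "Golgi apparatus"),
    label = c("cell", "extracellular region", "plasma membrane",
              "intracellular", "cytosol", "nucleus", "mitochondrion",
              "endoplasmic reticulum", "Golgi apparatus"),
    parent = c(NA, "cell", "cell", "cell", "intracellular", "intracellular",
               "intracellular", "intracellular", "intracellular"),
    depth = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    color = c("#FFFFFF", "#E8F4FA", "#D8E8D0", "#F7F3E3", "#FCE8D8",
              "#E3D8F0", "#F5D8D8", "#D8F0EC", "#F0E8D0"),
    stringsAsFactors = FALSE)
  new("CompartmentTree", nodes = nodes, root = "cell")
}

#' Read a compartment tree
#'
#' Accepts either a two/three-column parent-child TSV (`term_id`,
#' `parent`, optional `label`; the root has an empty parent) or a minimal
#' OBO subset (stanzas with `id:`, `name:`, `is_a:` lines).
#'
#' @param file Path.
#' @return A [CompartmentTree-class].
#' @export
readCompartmentTree <- function(file) {
  lines <- readLines(file)
  if (any(grepl("^\\[Term\\]", lines))) {
    return(parseOboTree(lines))
  }
  hasHeader <- grepl("term_id|parent", lines[1L])
  df <- read.delim(textConnection(lines), header = hasHeader,
                   stringsAsFactors = FALSE)
  if (!hasHeader) {
    names(df)[1:2] <- c("term_id", "parent")
    if (ncol(df) >= 3L) names(df)[3L] <- "label"
  }
  if (is.null(df$label)) df$label <- df$term_id
  df$parent[!nzchar(trimws(ifelse(is.na(df$parent), "", df$parent)))] <- NA
  buildTree(df)
}

parseOboTree <- function(lines) {
  ids <- character(0); labels <- character(0); parents <- character(0)
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    ids <<- c(ids, cur$id)
    labels <<- c(labels, if (is.null(cur$name)) cur$id else cur$name)
    parents <<- c(parents, if (is.null(cur$parent)) NA_character_ else cur$parent)
    cur <<- NULL
  }
  inTerm <- FALSE
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "[Term]") { flush(); inTerm <- TRUE; cur <- list(); next }
    if (grepl("^\\[", t)) { flush(); inTerm <- FALSE; next }
    if (!inTerm || !nzchar(t)) next
    if (startsWith(t, "id:")) cur$id <- trimws(sub("^id:", "", t))
    if (startsWith(t, "name:")) cur$name <- trimws(sub("^name:", "", t))
    if (startsWith(t, "is_a:")) {
      cur$parent <- trimws(strsplit(sub("^is_a:", "", t), "!", fixed = TRUE)[[1L]][1L])
    }
  }
  flush()
  buildTree(data.frame(term_id = ids, parent = parents, label = labels,
                       stringsAsFactors = FALSE))
}

buildTree <- function(df) {
  rootIdx <- which(is.na(df$parent))
  stopifnot2(length(rootIdx) == 1L, "tree must have exactly one root (empty parent)")
  root <- df$term_id[rootIdx]
  depth <- setNames(rep(NA_integer_, nrow(df)), df$term_id)
  depth[root] <- 0L
  repeat {
    prog <- FALSE
    for (i in seq_len(nrow(df))) {
      t <- df$term_id[i]
      if (!is.na(depth[t])) next
      p <- df$parent[i]
      if (!is.na(depth[p])) { depth[t] <- depth[p] + 1L; prog <- TRUE }
    }
    if (!prog) break
  }
  stopifnot2(!anyNA(depth), "tree contains unreachable nodes (cycle or missing parent)")
  pal <- grDevices::hcl.colors(max(nrow(df), 3L), "Pastel 1")
  nodes <- data.frame(term_id = df$term_id, label = df$label,
                      parent = df$parent, depth = unname(depth[df$term_id]),
                      color = pal[seq_len(nrow(df))], stringsAsFactors = FALSE)
  new("CompartmentTree", nodes = nodes, root = root)
}

#' Read a gene-to-compartment map
#'
#' Two-column TSV (`gene_id`, `cc_term`); a header line is optional. A
#' gene may map to several terms.
#'
#' @param file Path.
#' @return data.frame with columns `gene_id`, `cc_term`.
#' @export
readCompartmentMap <- function(file) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("gene_id|cc_term", first)
  df <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) names(df)[1:2] <- c("gene_id", "cc_term")
  df[c("gene_id", "cc_term")]
}
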