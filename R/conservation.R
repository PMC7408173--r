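#' Default physicochemical similarity grouping
#'
#' Residue classes treated as "similar" for percent-similarity scoring:
#' aliphatic/hydrophobic (AVLIM), aromatic (FYW), small hydroxyl (ST),
#' basic (KRH), acidic (DE), amide (NQ), cysteine (C), and
#' conformationally special (GP). Identical residues always count as
#' similar.
#'
#' @return Named list of character vectors with attribute `"name"`.
#' @export
similarity_groups <- function() {
  structure(list(aliphatic = c("A", "V", "L", "I", "M"),
                 aromatic = c("F", "Y", "W"),
                 hydroxyl = c("S", "T"),
                 basic = c("K", "R", "H"),
                 acidic = c("D", "E"),
                 amide = c("N", "Q"),
                 cysteine = "C",
                 special = c("G", "P")),
            name = "physicochemical_8")
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of equal-length gapped sequences
#'   (uppercase), class `alignment_block`.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  aln <- toupper(as.character(aa))
  names(aln) <- sub("\\s.*$", "", names(aa))
  as_alignment(aln)
}

#' Assemble an alignment block from gapped sequences
#'
#' @param sequences Named character vector of equal-length gapped residue
#'   strings (gap = `-`).
#' @return An `alignment_block`.
#' @export
as_alignment <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 2,
            !is.null(names(sequences)))
  sequences <- toupper(sequences)
  w <- nchar(sequences)
  if (length(unique(w)) != 1)
    stop("alignment rows differ in length: ",
         paste(unique(w), collapse = ", "))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*.-]*$", sequences)
  if (!all(ok))
    stop("non-amino-acid characters in sequence(s): ",
         paste(names(sequences)[!ok], collapse = ", "))
  structure(chartr(".", "-", sequences), class = "alignment_block")
}

aln_matrix <- function(block) {
  do.call(rbind, strsplit(unclass(block), ""))
}

#' Pairwise percent identity and similarity over an alignment
#'
#' Counts, over the selected alignment columns, positions where both
#' sequences carry a residue: identical pairs and similar pairs (identical,
#' or members of the same [similarity_groups()] class). Percentages are
#' taken relative to a denominator convention:
#' \describe{
#'   \item{`shortest`}{ungapped length of the shorter sequence over the
#'     region (default, matching the common web-scorer default);}
#'   \item{`alignment`}{number of columns in the region;}
#'   \item{`mean`}{mean of the two ungapped lengths.}
#' }
#'
#' @param block An `alignment_block` (or named gapped character vector).
#' @param pair Character vector of two sequence ids.
#' @param region Optional column window `c(first, last)` (1-based,
#'   inclusive); default all columns.
#' @param convention Denominator convention.
#' @param grouping Similarity grouping (default [similarity_groups()]).
#' @return data.frame with `id1`, `id2`, `region_start`, `region_end`,
#'   `identity`, `similarity` (percent), `denominator`, `convention`,
#'   `grouping`.
#' @export
pairwise_scores <- function(block, pair, region = NULL,
                            convention = c("shortest", "alignment", "mean"),
                            grouping = similarity_groups()) {
  convention <- match.arg(convention)
  if (!inherits(block, "alignment_block")) block <- as_alignment(block)
  stopifnot(length(pair) == 2)
  missing <- setdiff(pair, names(block))
  if (length(missing))
    stop("sequence id(s) not in alignment: ", paste(missing, collapse = ", "))
  w <- nchar(block[[1]])
  if (is.null(region)) region <- c(1L, w)
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= w,
            region[1] <= region[2])
  cols <- region[1]:region[2]
  s1 <- strsplit(substr(unclass(block)[[pair[1]]], region[1], region[2]), "")[[1]]
  s2 <- strsplit(substr(unclass(block)[[pair[2]]], region[1], region[2]), "")[[1]]
  res1 <- s1 != "-"
  res2 <- s2 != "-"
  both <- res1 & res2
  ident <- sum(both & s1 == s2)
  cls <- character(0)
  for (nm in names(grouping)) cls[grouping[[nm]]] <- nm
  same_class <- both & !is.na(cls[s1]) & !is.na(cls[s2]) & cls[s1] == cls[s2]
  simil <- sum((both & s1 == s2) | same_class)
  len1 <- sum(res1); len2 <- sum(res2)
  denom <- switch(convention,
                  shortest = min(len1, len2),
                  alignment = length(cols),
                  mean = (len1 + len2) / 2)
  if (denom == 0) stop("empty region: no residues in the selected columns")
  data.frame(id1 = pair[1], id2 = pair[2],
             region_start = region[1], region_end = region[2],
             identity = 100 * ident / denom,
             similarity = 100 * simil / denom,
             denominator = denom, convention = convention,
             grouping = attr(grouping, "name") %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map ungapped residue coordinates to alignment columns
#'
#' @param block An `alignment_block`.
#' @param id Sequence id.
#' @param positions Ungapped residue positions (1-based).
#' @return Alignment column indices.
#' @export
residue_to_column <- function(block, id, positions) {
  if (!inherits(block, "alignment_block")) block <- as_alignment(block)
  s <- strsplit(unclass(block)[[id]], "")[[1]]
  res_cols <- which(s != "-")
  if (any(positions < 1 | positions > length(res_cols)))
    stop("position(s) exceed ungapped length ", length(res_cols),
         " of '", id, "'")
  res_cols[positions]
}

#' Extract a domain window from an alignment
#'
#' Given per-sequence residue spans (ungapped, 1-based, inclusive; e.g.
#' domain annotations), returns the minimal alignment column window
#' covering every span, preserving the alignment.
#'
#' @param block An `alignment_block`.
#' @param spans data.frame with columns `id`, `start`, `end` (one row per
#'   sequence to constrain; sequences absent from `spans` do not constrain
#'   the window).
#' @return An `alignment_block` over the extracted columns, with attribute
#'   `"columns"` recording the window.
#' @export
extract_domain <- function(block, spans) {
  if (!inherits(block, "alignment_block")) block <- as_alignment(block)
  stopifnot(is.data.frame(spans),
            all(c("id", "start", "end") %in% names(spans)))
  missing <- setdiff(spans$id, names(block))
  if (length(missing))
    stop("span id(s) not in alignment: ", paste(missing, collapse = ", "))
  cols <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    range(residue_to_column(block, spans$id[i],
                            c(spans$start[i], spans$end[i])))
  }))
  win <- c(min(cols), max(cols))
  out <- vapply(unclass(block), substr, "", win[1], win[2])
  structure(as_alignment(out), columns = win, class = "alignment_block")
}
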