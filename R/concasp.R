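#' Concatenate ASPs into maximal ConcASPs
#'
#' Within every allergenic protein, all (possibly overlapping) occurrences
#' of all ASPs are located and occurrence intervals that overlap or abut are
#' merged; each maximal merged interval yields one candidate string, which is
#' by construction an overlapped concatenation of its constituent ASPs
#' witnessed by that protein (an empty overlap is plain concatenation).
#' Candidates identical in sequence are deduplicated across proteins with
#' their witnesses pooled, and finally only maximal candidates are kept:
#' any candidate that is a substring of another is dropped.
#'
#' @param asps character vector of ASP sequences (or a [select_asps()]
#'   result, from which the `pattern` column is taken).
#' @param dataset a [protein_dataset()]; only allergenic proteins are
#'   scanned.
#' @return A `data.frame` with columns `seq`, `length`, `n_constituents`,
#'   `n_witnesses`, plus list-columns `constituents` (contributing ASP
#'   strings) and `witnesses` (data.frames of `protein_id`, `start`, `end`
#'   with 0-based half-open coordinates).
#' @examples
#' d <- protein_dataset("p", "MKRRELEK", "x", 1)
#' find_concasps(c("MKRR", "RREL"), d)$seq  # "MKRREL"
#' @export
find_concasps <- function(asps, dataset) {
  if (is.data.frame(asps)) asps <- asps$pattern
  asps <- unique(as.character(asps))
  stopifnot(length(asps) >= 1L)
  pos_idx <- which(dataset$label == 1L)
  occ <- cpp_find_occurrences(asps, dataset$sequence[pos_idx])
  if (nrow(occ) == 0L) {
    return(data.frame(seq = character(0), length = integer(0),
                      n_constituents = integer(0), n_witnesses = integer(0)))
  }
  occ$protein <- pos_idx[occ$protein]  # back to dataset row indices

  cand_seq <- character(0)
  cand_const <- list()
  cand_wit <- list()
  for (p in unique(occ$protein)) {
    o <- occ[occ$protein == p, , drop = FALSE]
    o <- o[order(o$start, o$end), , drop = FALSE]
    s <- dataset$sequence[p]
    cur_start <- o$start[1]
    cur_end <- o$end[1]
    members <- o$pattern[1]
    flush <- function(start, end, members) {
      cand_seq[[length(cand_seq) + 1L]] <<- substr(s, start + 1L, end)
      cand_const[[length(cand_const) + 1L]] <<- unique(asps[members])
      cand_wit[[length(cand_wit) + 1L]] <<-
        data.frame(protein_id = dataset$id[p], start = start, end = end,
                   stringsAsFactors = FALSE)
    }
    if (nrow(o) > 1L) {
      for (i in 2:nrow(o)) {
        if (o$start[i] <= cur_end) {  # overlap or abut (half-open intervals)
          cur_end <- max(cur_end, o$end[i])
          members <- c(members, o$pattern[i])
        } else {
          flush(cur_start, cur_end, members)
          cur_start <- o$start[i]
          cur_end <- o$end[i]
          members <- o$pattern[i]
        }
      }
    }
    flush(cur_start, cur_end, members)
  }

  # deduplicate identical candidate sequences, pooling provenance
  grp <- split(seq_along(cand_seq), cand_seq)
  useq <- names(grp)
  uconst <- lapply(grp, function(ix) unique(unlist(cand_const[ix])))
  uwit <- lapply(grp, function(ix) unique(do.call(rbind, cand_wit[ix])))

  keep <- cpp_maximal_keep(useq)
  out <- data.frame(seq = useq[keep], length = nchar(useq[keep]),
                    n_constituents = lengths(uconst)[keep],
                    n_witnesses = vapply(uwit, nrow, integer(1))[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$constituents <- unname(uconst[keep])
  out$witnesses <- unname(uwit[keep])
  out <- out[order(-out$length, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximal (substring-free) subset of a string set
#'
#' Keeps the strings that are not substrings of any other input string;
#' duplicates are collapsed to one copy. Every input string is a substring
#' of some output string.
#'
#' @param candidates character vector.
#' @return Character vector, pairwise substring-free, in input order.
#' @examples
#' maximal_filter(c("MKRR", "MKRREL"))  # "MKRREL"
#' @export
maximal_filter <- function(candidates) {
  candidates <- as.character(candidates)
  candidates[cpp_maximal_keep(candidates)]
}

#' Exact-inclusion matching of peptide queries against ConcASPs
#'
#' For each query peptide, lists the target sequences containing it as a
#' contiguous substring (the inclusion check used to compare mined patterns
#' with known IgE-epitope peptides).
#'
#' @param queries character vector of peptide sequences.
#' @param targets character vector of target sequences, or a
#'   [find_concasps()] result (its `seq` column is used).
#' @return A list with `matches` (data.frame `query`, `target`), and counts
#'   `n_queries_matched`, `n_targets_matched`.
#' @export
exact_inclusion_match <- function(queries, targets) {
  if (is.data.frame(targets)) targets <- targets$seq
  queries <- as.character(queries)
  targets <- as.character(targets)
  hits <- lapply(queries, function(q) targets[grepl(q, targets, fixed = TRUE)])
  matches <- data.frame(
    query = rep.int(queries, lengths(hits)),
    target = unlist(hits, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  list(matches = matches,
       n_queries_matched = sum(lengths(hits) > 0L),
       n_targets_matched = length(unique(matches$target)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ConcASPs as FASTA and/or TSV
#'
#' @param concasps a [find_concasps()] result.
#' @param fasta,tsv output paths (either may be `NULL`).
#' @param header optional comment line for the TSV.
#' @return Invisibly, the paths written.
#' @export
write_concasps <- function(concasps, fasta = NULL, tsv = NULL, header = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::AAStringSet(concasps$seq)
    names(ss) <- sprintf("concasp_%d constituents=%d witnesses=%d",
                         seq_len(nrow(concasps)), concasps$n_constituents,
                         concasps$n_witnesses)
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(concasps[, c("seq", "length", "n_constituents", "n_witnesses")],
                con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta, tsv = tsv))
}
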