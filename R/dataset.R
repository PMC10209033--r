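#' Labeled, categorized protein datasets
#'
#' A protein dataset is an ordered collection of records, each holding a
#' unique `id`, an uppercase amino-acid `sequence`, a biological `category`
#' name, and a binary allergenicity `label` (+1 allergen, -1 nonallergen).
#' It is stored as a classed `data.frame` so the usual subsetting and
#' inspection idioms apply.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of amino-acid sequences; forced to
#'   uppercase. Must be nonempty and alphabetic.
#' @param category character vector of biological category names.
#' @param label numeric/character vector coercible to +1/-1 (see
#'   [normalize_labels()]).
#' @param strict reject sequences containing residues outside the 20
#'   standard amino acids (ambiguity codes B, J, O, U, X, Z are otherwise
#'   accepted verbatim).
#' @return An object of class `protein_dataset` (a `data.frame` with columns
#'   `id`, `sequence`, `category`, `label`).
#' @examples
#' d <- protein_dataset(c("p1", "p2"), c("MKRREL", "KRRE"),
#'                      c("apple", "apple"), c(1, -1))
#' n_pos(d)
#' @export
protein_dataset <- function(id, sequence, category, label, strict = FALSE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  category <- as.character(category)
  label <- normalize_labels(label)
  stopifnot(length(id) == length(sequence),
            length(id) == length(category),
            length(id) == length(label))
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- which(is.na(sequence) | !grepl("^[A-Z]+$", sequence))
  if (length(bad)) {
    stop("record(s) ", paste(head(bad, 5), collapse = ", "),
         ": sequence must be a nonempty string of uppercase letters")
  }
  if (strict) {
    nonstd <- which(grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")),
                          sequence))
    if (length(nonstd)) {
      stop("record(s) ", paste(head(nonstd, 5), collapse = ", "),
           ": nonstandard residue(s) present (strict mode)")
    }
  }
  out <- data.frame(id = id, sequence = sequence, category = category,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("protein_dataset", "data.frame")
  out
}

#' Normalize allergenicity labels to +1/-1
#'
#' Accepts the numeric codes `1`/`-1` (also `+1`) and the documented text
#' aliases (case-insensitive): `allergen`, `pos`, `positive` for +1;
#' `nonallergen`, `non-allergen`, `neg`, `negative` for -1. Additional
#' aliases can be supplied.
#'
#' @param x vector of raw labels.
#' @param aliases optional named list with elements `pos` and `neg`, each a
#'   character vector of extra accepted spellings.
#' @return Integer vector of +1/-1.
#' @export
normalize_labels <- function(x, aliases = NULL) {
  pos <- c("1", "+1", "allergen", "pos", "positive")
  neg <- c("-1", "nonallergen", "non-allergen", "neg", "negative")
  if (!is.null(aliases)) {
    pos <- c(pos, tolower(as.character(aliases$pos)))
    neg <- c(neg, tolower(as.character(aliases$neg)))
  }
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(key))
  out[key %in% pos] <- 1L
  out[key %in% neg] <- -1L
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("row(s) ", paste(head(bad, 5), collapse = ", "),
         ": label not in {+1, -1} or a known alias (got ",
         paste(unique(x[head(bad, 5)]), collapse = ", "), ")")
  }
  out
}

#' @rdname protein_dataset
#' @param x a `protein_dataset`.
#' @export
n_proteins <- function(x) nrow(x)

#' @rdname protein_dataset
#' @export
n_pos <- function(x) sum(x$label == 1L)

#' @rdname protein_dataset
#' @export
n_neg <- function(x) sum(x$label == -1L)

#' Read a labeled protein dataset
#'
#' Reads the native delimited format (columns `id`, `sequence`, `category`,
#' `label`, header required) or a FASTA file paired with a metadata table
#' keyed by FASTA record id. Sequences are uppercased on read; labels are
#' normalized to +1/-1.
#'
#' @param path path to the TSV/CSV or FASTA file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"fasta"`.
#' @param meta for FASTA input, path to a TSV with columns `id`, `category`,
#'   `label`.
#' @param aliases passed to [normalize_labels()].
#' @param strict passed to [protein_dataset()].
#' @return A [protein_dataset()] with rows in file order.
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "csv", "fasta"),
                         meta = NULL, aliases = NULL, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv",
                     fa = "fasta", fasta = "fasta", faa = "fasta",
                     "tsv")
  }
  if (format == "fasta") {
    if (is.null(meta)) stop("FASTA input requires a metadata table (meta=)")
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    md <- read.delim(meta, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("id", "category", "label")
    miss <- setdiff(need, names(md))
    if (length(miss)) stop("metadata missing column(s): ",
                           paste(miss, collapse = ", "))
    idx <- match(ids, md$id)
    if (anyNA(idx)) {
      stop("FASTA record(s) without metadata: ",
           paste(head(ids[is.na(idx)], 5), collapse = ", "))
    }
    df <- data.frame(id = ids, sequence = as.character(aa),
                     category = md$category[idx], label = md$label[idx],
                     stringsAsFactors = FALSE)
  } else {
    reader <- if (format == "csv") read.csv else read.delim
    df <- reader(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("id", "sequence", "category", "label")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  lab <- tryCatch(normalize_labels(df$label, aliases), error = function(e) {
    # report file line numbers (header is line 1)
    stop(conditionMessage(e), " [data rows count from line 2 of ", path, "]",
         call. = FALSE)
  })
  protein_dataset(df$id, df$sequence, df$category, lab, strict = strict)
}

#' Write a protein dataset as TSV
#'
#' @param dataset a [protein_dataset()].
#' @param path output path.
#' @return `path`, invisibly. `read_dataset(write_dataset(d, f))` round-trips
#'   the data model.
#' @export
write_dataset <- function(dataset, path) {
  write.table(as.data.frame(dataset)[, c("id", "sequence", "category", "label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify biological categories
#'
#' Each category is assigned exactly one type: `paired` (contains allergens
#' and nonallergens), `positive_only` (allergens only), or `negative_only`
#' (nonallergens only). The distinction drives the category-specificity
#' screen for allergen-specific patterns.
#'
#' @param dataset a [protein_dataset()].
#' @return A `data.frame` of class `category_profile` with columns
#'   `category`, `type`, `count_pos`, `count_neg`, in order of first
#'   appearance.
#' @export
classify_categories <- function(dataset) {
  stopifnot(nrow(dataset) > 0)
  cats <- unique(dataset$category)
  cp <- vapply(cats, function(g) sum(dataset$label == 1L & dataset$category == g),
               integer(1))
  cn <- vapply(cats, function(g) sum(dataset$label == -1L & dataset$category == g),
               integer(1))
  type <- ifelse(cp > 0L & cn > 0L, "paired",
                 ifelse(cp > 0L, "positive_only", "negative_only"))
  out <- data.frame(category = cats, type = type,
                    count_pos = cp, count_neg = cn,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("category_profile", "data.frame")
  out
}

#' Summarize a protein dataset
#'
#' @param dataset a [protein_dataset()].
#' @return A list with counts (`n`, `n_pos`, `n_neg`), sequence length
#'   statistics (mean/min/max), and category type counts.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(nrow(dataset) > 0)
  len <- nchar(dataset$sequence)
  prof <- classify_categories(dataset)
  tt <- table(factor(prof$type,
                     levels = c("paired", "positive_only", "negative_only")))
  list(n = nrow(dataset), n_pos = n_pos(dataset), n_neg = n_neg(dataset),
       length_mean = mean(len), length_min = min(len), length_max = max(len),
       n_categories = nrow(prof),
       category_types = as.list(as.integer(tt)) |>
         stats::setNames(names(tt)))
}

#' @export
print.protein_dataset <- function(x, n = 6L, ...) {
  cat(sprintf("protein_dataset: %d proteins (%d allergen, %d nonallergen), %d categories\n",
              nrow(x), n_pos(x), n_neg(x), length(unique(x$category))))
  shown <- head(as.data.frame(x), n)
  long <- nchar(shown$sequence) > 40
  shown$sequence[long] <- paste0(substr(shown$sequence[long], 1, 37), "...")
  print(shown)
  if (nrow(x) > n) cat(sprintf("... and %d more proteins\n", nrow(x) - n))
  invisible(x)
}
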