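#' @useDynLib m5ugraph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict rbinom runif sd setNames
#' @importFrom utils read.delim write.table
NULL

M5U_ALPHABET <- c("A", "C", "G", "U")

#' Construct a labeled window dataset
#'
#' A dataset is an ordered collection of fixed-length RNA windows with a
#' uridine at the centre, each carrying a label (\code{"positive"},
#' \code{"negative"} or \code{"unknown"}) and optional group tags such as
#' profiling technique or cell line. Sequences are normalized to uppercase
#' RNA (\code{T} becomes \code{U}) before validation.
#'
#' @param id character vector of unique window ids.
#' @param seq character vector of sequences over \code{A,C,G,U} (DNA input
#'   with \code{T} is accepted and normalized).
#' @param label character vector; one of \code{positive}, \code{negative},
#'   \code{unknown}. Recycled if length 1.
#' @param groups optional data.frame of per-window tags (e.g. columns
#'   \code{technique}, \code{cell}).
#' @param L window length; must be odd. All sequences must have this length.
#' @param center_check if \code{TRUE} (default) a non-U centre is an error;
#'   otherwise a warning.
#' @return an object of class \code{m5u_dataset}.
#' @export
m5u_dataset <- function(id, seq, label = "unknown", groups = NULL, L = 41L,
                        center_check = TRUE) {
  id <- as.character(id)
  seq <- normalize_seq(seq)
  label <- rep_len(as.character(label), length(seq))
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  if (anyDuplicated(id))
    stop("duplicate window ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (L %% 2L == 0L) stop("window length L must be odd, got ", L)
  bad <- setdiff(unique(label), c("positive", "negative", "unknown"))
  if (length(bad)) stop("invalid labels: ", paste(bad, collapse = ", "))
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    if (nrow(groups) != length(seq))
      stop("`groups` must have one row per window")
  }
  ds <- structure(list(id = id, seq = seq, label = label,
                       groups = groups, L = as.integer(L)),
                  class = "m5u_dataset")
  validate_windows(ds, center_check = center_check)
  ds
}

normalize_seq <- function(seq) {
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)))
  gsub("T", "U", seq, fixed = TRUE)
}

validate_windows <- function(ds, center_check = TRUE) {
  L <- ds$L
  n <- nchar(ds$seq)
  if (any(n != L)) {
    i <- which(n != L)[1L]
    stop("window '", ds$id[i], "' has length ", n[i], ", expected ", L)
  }
  ok <- !grepl(paste0("[^", paste(M5U_ALPHABET, collapse = ""), "]"), ds$seq)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop("window '", ds$id[i], "' contains characters outside A,C,G,U")
  }
  center <- substr(ds$seq, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
  if (any(center != "U")) {
    i <- which(center != "U")[1L]
    msg <- paste0("window '", ds$id[i], "' has centre nucleotide '", center[i],
                  "', expected U")
    if (center_check) stop(msg) else warning(msg)
  }
  invisible(ds)
}

#' @export
print.m5u_dataset <- function(x, ...) {
  cat("m5u_dataset: ", length(x$id), " windows of length ", x$L, "\n", sep = "")
  tab <- table(factor(x$label, levels = c("positive", "negative", "unknown")))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$groups))
    cat("  group tags:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.m5u_dataset <- function(x) length(x$id)

#' Subset a dataset by index
#' @param x an \code{m5u_dataset}.
#' @param i integer or logical index.
#' @param ... ignored.
#' @export
`[.m5u_dataset` <- function(x, i, ...) {
  structure(list(id = x$id[i], seq = x$seq[i], label = x$label[i],
                 groups = if (is.null(x$groups)) NULL else x$groups[i, , drop = FALSE],
                 L = x$L),
            class = "m5u_dataset")
}

#' Read labeled RNA windows from FASTA
#'
#' Reads fixed-length windows from a FASTA file. Labels and group tags are
#' taken from \code{key=value} tokens in the description line
#' (e.g. \code{>s1 label=positive technique=miCLIP}); a side-car TSV with
#' columns \code{id}, \code{label} (and optional group columns) takes
#' precedence when supplied and must cover every id. \code{T} is normalized
#' to \code{U} and lowercase to uppercase.
#'
#' @param fasta_path path to a FASTA file of equal-length windows.
#' @param labels optional path to a tab-delimited label table.
#' @param L expected window length (odd), default 41.
#' @param center_check error (default) or merely warn when the centre
#'   nucleotide is not U.
#' @return an \code{m5u_dataset} in file order.
#' @export
read_windows <- function(fasta_path, labels = NULL, L = 41L, center_check = TRUE) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  recs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA '", fasta_path,
                                            "': ", conditionMessage(e)))
  desc <- names(recs)
  id <- sub("[[:space:]].*$", "", desc)
  seqs <- as.character(recs)
  meta <- parse_desc_tokens(desc)
  label <- if ("label" %in% names(meta)) meta$label else rep("unknown", length(id))
  label[is.na(label)] <- "unknown"
  groups <- meta[setdiff(names(meta), "label")]
  groups <- if (length(groups)) as.data.frame(groups, stringsAsFactors = FALSE) else NULL
  if (!is.null(labels)) {
    tab <- read.delim(labels, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("id", "label") %in% names(tab)))
      stop("label table must have 'id' and 'label' columns")
    miss <- setdiff(id, tab$id)
    if (length(miss))
      stop("label table missing ids: ", paste(utils::head(miss, 5L), collapse = ", "))
    m <- match(id, tab$id)
    label <- tab$label[m]
    extra <- setdiff(names(tab), c("id", "label"))
    if (length(extra)) groups <- tab[m, extra, drop = FALSE]
  }
  m5u_dataset(id, seqs, label, groups = groups, L = L, center_check = center_check)
}

parse_desc_tokens <- function(desc) {
  toks <- regmatches(desc, gregexpr("[A-Za-z_]+=[^[:space:]]+", desc))
  keys <- unique(unlist(lapply(toks, function(t) sub("=.*$", "", t))))
  out <- lapply(keys, function(k) {
    vapply(toks, function(t) {
      hit <- grep(paste0("^", k, "="), t, value = TRUE)
      if (length(hit)) sub("^[^=]+=", "", hit[1L]) else NA_character_
    }, character(1L))
  })
  names(out) <- keys
  out
}

#' Write a dataset to FASTA plus a label table
#'
#' @param ds an \code{m5u_dataset}.
#' @param fasta_path output FASTA path.
#' @param labels_path optional output path for the tab-delimited label table
#'   (columns \code{id}, \code{label}, plus any group columns).
#' @return \code{fasta_path}, invisibly.
#' @export
write_windows <- function(ds, fasta_path, labels_path = NULL) {
  hdr <- paste0(ds$id, " label=", ds$label)
  if (!is.null(ds$groups))
    for (g in names(ds$groups))
      hdr <- paste0(hdr, " ", g, "=", ds$groups[[g]])
  x <- Biostrings::BStringSet(ds$seq)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, fasta_path, width = 80L)
  if (!is.null(labels_path)) {
    tab <- data.frame(id = ds$id, label = ds$label, stringsAsFactors = FALSE)
    if (!is.null(ds$groups)) tab <- cbind(tab, ds$groups)
    write.table(tab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Construct a named-block feature matrix
#'
#' A feature matrix is a dense samples-by-features matrix partitioned into
#' named blocks (one per encoder or embedding method); columns are named
#' \code{"<block>.<index>"} so the block schema round-trips through TSV.
#'
#' @param ids ordered sample ids (row order).
#' @param X numeric matrix, \code{length(ids)} rows.
#' @param blocks data.frame with columns \code{name} and \code{n_cols};
#'   \code{sum(n_cols)} must equal \code{ncol(X)}.
#' @return an object of class \code{m5u_features}.
#' @export
m5u_features <- function(ids, X, blocks) {
  X <- as.matrix(X)
  blocks <- data.frame(name = as.character(blocks$name),
                       n_cols = as.integer(blocks$n_cols),
                       stringsAsFactors = FALSE)
  if (nrow(X) != length(ids)) stop("row count must match ids")
  if (sum(blocks$n_cols) != ncol(X))
    stop("block widths (", sum(blocks$n_cols), ") do not sum to ncol(X) (",
         ncol(X), ")")
  if (any(grepl(".", blocks$name, fixed = TRUE)))
    stop("block names must not contain '.'")
  if (anyNA(X)) stop("feature matrix contains missing values")
  colnames(X) <- unlist(mapply(function(nm, k) paste0(nm, ".", seq_len(k)),
                               blocks$name, blocks$n_cols, SIMPLIFY = FALSE))
  rownames(X) <- NULL
  structure(list(ids = as.character(ids), X = X, blocks = blocks),
            class = "m5u_features")
}

#' @export
print.m5u_features <- function(x, ...) {
  cat("m5u_features: ", length(x$ids), " samples x ", ncol(x$X), " features\n",
      sep = "")
  cat("  blocks:", paste0(x$blocks$name, "(", x$blocks$n_cols, ")",
                          collapse = " "), "\n")
  invisible(x)
}

#' Write / read a feature matrix as TSV
#'
#' The TSV carries the block schema in its header (\code{block.index} column
#' names) and the sample id in the first column, so
#' \code{read_feature_matrix(write_feature_matrix(fm, p))} reproduces
#' \code{fm} up to float formatting (1e-9).
#'
#' @param fm an \code{m5u_features} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "m5u_features"))
  df <- data.frame(id = fm$ids, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(fm$X)) {
    vals <- as.data.frame(apply(fm$X, 2L, function(col) sprintf("%.12g", col),
                                simplify = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
      vals <- as.data.frame(matrix(character(0), 0L, ncol(fm$X),
                                   dimnames = list(NULL, colnames(fm$X))),
                            check.names = FALSE)
    df <- cbind(df, vals)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!length(df) || names(df)[1L] != "id")
    stop("feature matrix file must have 'id' as first column: ", path)
  cn <- names(df)[-1L]
  if (anyDuplicated(cn)) stop("duplicate feature columns in ", path)
  bad <- !grepl("^[^.]+\\.[0-9]+$", cn)
  if (any(bad)) stop("malformed feature column name(s): ",
                     paste(utils::head(cn[bad], 3L), collapse = ", "))
  blk <- sub("\\.[0-9]+$", "", cn)
  blocks <- data.frame(name = rle(blk)$values, n_cols = rle(blk)$lengths,
                       stringsAsFactors = FALSE)
  if (anyDuplicated(blocks$name)) stop("non-contiguous feature blocks in ", path)
  X <- matrix(as.numeric(as.matrix(df[-1L])), nrow = nrow(df), ncol = length(cn))
  m5u_features(df$id, X, blocks)
}
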