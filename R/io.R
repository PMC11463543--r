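#' Experimental design table
#'
#' Maps TMT reporter channels to the factors of an organelle-IP experiment:
#' tagged vs untagged-control condition, IP type (endosome via EEA1 or
#' lysosome via TMEM192), cell state and biological replicate.
#'
#' @param channel_id character channel identifiers (unique).
#' @param condition "tagged" or "control" per channel.
#' @param ip_type "endo" or "lyso" per channel.
#' @param cell_state "hESC", "iNeuron" or "other" per channel.
#' @param replicate integer replicate index per channel.
#' @return a \code{data.frame} of class \code{design_table}.
#' @export
design_table <- function(channel_id, condition, ip_type, cell_state,
                         replicate) {
  d <- data.frame(channel_id = as.character(channel_id),
                  condition = as.character(condition),
                  ip_type = as.character(ip_type),
                  cell_state = as.character(cell_state),
                  replicate = as.integer(replicate),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$channel_id))
    stop("duplicate channel ids: ",
         paste(unique(d$channel_id[duplicated(d$channel_id)]), collapse = ", "))
  if (!all(d$condition %in% c("tagged", "control")))
    stop("condition must be 'tagged' or 'control'")
  if (!all(d$ip_type %in% c("endo", "lyso")))
    stop("ip_type must be 'endo' or 'lyso'")
  if (!all(d$cell_state %in% c("hESC", "iNeuron", "other")))
    stop("cell_state must be 'hESC', 'iNeuron' or 'other'")
  for (s in split(d, paste(d$ip_type, d$cell_state))) {
    if (sum(s$condition == "tagged") < 2L || sum(s$condition == "control") < 2L)
      stop("stratum ", s$ip_type[1], "/", s$cell_state[1],
           " needs >= 2 tagged and >= 2 control channels")
  }
  class(d) <- c("design_table", "data.frame")
  d
}

#' Construct an intensity matrix
#'
#' Protein-by-channel reporter intensities paired with their design table.
#' Non-finite or negative intensities are recorded as missing; zero is
#' treated as missing too, because the quantitative pipeline works on the
#' log2 scale.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   channels in columns (colnames = channel ids).
#' @param design a [design_table()] covering every column.
#' @param log2_scale logical; TRUE once values are log2-transformed.
#' @return an object of class \code{intensity_matrix}.
#' @export
intensity_matrix <- function(values, design, log2_scale = FALSE) {
  stopifnot(is.matrix(values), inherits(design, "design_table"))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry protein rownames and channel colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  missing_cols <- setdiff(design$channel_id, colnames(values))
  if (length(missing_cols))
    stop("channels in design absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  extra_cols <- setdiff(colnames(values), design$channel_id)
  if (length(extra_cols))
    stop("channels in matrix absent from design: ",
         paste(extra_cols, collapse = ", "))
  values <- values[, design$channel_id, drop = FALSE]
  if (!log2_scale) values[!is.finite(values) | values <= 0] <- NA_real_
  structure(list(values = values, design = design, log2_scale = log2_scale),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "channels",
      if (x$log2_scale) "(log2 scale)" else "(reporter scale)", "\n")
  invisible(x)
}

#' Read a protein-by-channel intensity TSV
#'
#' Expects one `protein` identifier column plus one numeric column per
#' channel named in the design; channels are returned in design order.
#'
#' @param path TSV file with a header row.
#' @param design a [design_table()].
#' @return an [intensity_matrix()].
#' @export
read_intensity_table <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein" %in% names(df))
    stop("intensity table must have a 'protein' column: ", path)
  missing_cols <- setdiff(design$channel_id, names(df))
  if (length(missing_cols))
    stop("channel column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c("protein", design$channel_id))
  if (length(extra))
    stop("channel column(s) absent from the design in ", path, ": ",
         paste(extra, collapse = ", "))
  dups <- unique(df$protein[duplicated(df$protein)])
  if (length(dups))
    stop("duplicate protein ids in ", path, ": ", paste(dups, collapse = ", "))
  m <- as.matrix(df[, design$channel_id, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein
  intensity_matrix(m, design)
}

#' Write an intensity matrix as TSV
#'
#' Deterministic: proteins in row order, channels in design order, full
#' double precision so a write/read round trip is value-exact.
#'
#' @param m an [intensity_matrix()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_intensity_table <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  df <- data.frame(protein = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path, sort_by = NULL)
}

#' Read protein sequences from FASTA
#'
#' Wrap-agnostic; the record id is the first whitespace-delimited token of
#' the header. Parsing is delegated to Biostrings.
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width (default 60).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then member identifiers, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return a named list of character vectors of class
#'   \code{geneset_collection}, with the set descriptions in
#'   \code{attr(,"descriptions")}.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0),
                     class = "geneset_collection"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 2L
  if (any(short))
    stop("malformed GMT line ", which(short)[1], " in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  structure(sets,
            descriptions = stats::setNames(vapply(parts, `[`, "", 2L),
                                           names(sets)),
            class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#'
#' Sets in alphabetical name order, members in their stored order.
#'
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  ord <- order(names(sets))
  lines <- vapply(ord, function(i) {
    paste(c(names(sets)[i], desc[[names(sets)[i]]], sets[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a records table as deterministic TSV
#'
#' Stable column order (as given) and an optional stable row sort so repeated
#' runs produce byte-identical files. Numeric columns are written at full
#' double precision.
#'
#' @param records a data.frame.
#' @param path output file.
#' @param sort_by column name(s) to sort rows by, or NULL to keep row order.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path, sort_by = names(records)[1]) {
  stopifnot(is.data.frame(records))
  if (!is.null(sort_by) && nrow(records) > 0) {
    records <- records[do.call(order, records[sort_by]), , drop = FALSE]
  }
  fmt <- function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE)
      }, "")
      out
    } else as.character(col)
  }
  out <- as.data.frame(lapply(records, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(records)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Join and split semicolon-delimited multi-label columns
#'
#' Annotation TSVs store multi-label fields (compartments, gene sets,
#' domains, families) as semicolon-joined strings; these helpers convert
#' between that representation and lists of character vectors.
#'
#' @param x for \code{join_labels}, a list of character vectors; for
#'   \code{split_labels}, a character vector of joined labels.
#' @return the other representation.
#' @export
join_labels <- function(x) vapply(x, function(v) paste(v, collapse = ";"), "")

#' @rdname join_labels
#' @export
split_labels <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}
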