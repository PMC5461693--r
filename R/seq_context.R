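#' @useDynLib sgdesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm binomial plogis quantile rnorm runif sd setNames
#' @importFrom utils read.delim write.table combn head
NULL

BASES <- c("A", "C", "G", "T")
DINUCS <- sort(as.vector(outer(BASES, BASES, paste0)))

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Locate spacer and PAM within a target context
#'
#' The 40 bp context is laid out as 10 nt 5' flank, 20 nt spacer, NGG PAM and
#' 7 nt 3' flank, which is the only arrangement that places the PAM GG at
#' positions 32-33 with the spacer immediately PAM-proximal. For 19 nt spacers
#' the layout is PAM-anchored (position 11 joins the 5' flank). In 30 bp mode
#' the layout is 4 nt flank + spacer + NGG + 3 nt flank (GG at 26-27).
#' All coordinates are 1-based inclusive.
#'
#' @param window context width, 40 or 30.
#' @param spacer_len spacer length, 20 or 19.
#' @return named integer vector with `spacer_start`, `spacer_end`, `pam_start`
#'   (position of the PAM 'N'; the GG occupies the next two positions).
#' @export
#' @examples
#' locate_spacer(40, 20)  # spacer 11..30, PAM N at 31, GG at 32-33
locate_spacer <- function(window = 40L, spacer_len = 20L) {
  window <- as.integer(window)
  spacer_len <- as.integer(spacer_len)
  if (!window %in% c(40L, 30L)) stop("window must be 40 or 30, got ", window)
  if (!spacer_len %in% c(20L, 19L)) stop("spacer_len must be 20 or 19, got ", spacer_len)
  pam_start <- if (window == 40L) 31L else 25L
  c(spacer_start = pam_start - spacer_len, spacer_end = pam_start - 1L,
    pam_start = pam_start)
}

# positions excluded from position-dependent encodings: the fixed PAM GG
pam_gg_positions <- function(window = 40L) {
  pam <- unname(locate_spacer(window, 20L)["pam_start"])
  c(pam + 1L, pam + 2L)
}

validate_context <- function(sequence, window, spacer_len) {
  if (is.na(sequence) || !nzchar(sequence)) return("empty sequence")
  if (nchar(sequence) != window) {
    return(sprintf("sequence length %d != window %d", nchar(sequence), window))
  }
  if (grepl("[^ACGT]", sequence)) return("non-ACGT characters in sequence")
  gg <- pam_gg_positions(window)
  if (substr(sequence, gg[1], gg[2]) != "GG") {
    return(sprintf("PAM GG not found at positions %d-%d", gg[1], gg[2]))
  }
  NULL
}

#' Construct a validated sgRNA context dataset
#'
#' @param df data.frame with columns `id`, `sequence` and optionally `label`
#'   (0/1 efficiency) and `gene`.
#' @param window context width in bp (40 or 30).
#' @param spacer_len spacer length (20 or 19).
#' @param name dataset name.
#' @return an object of class `sgrna_dataset`: the validated data.frame with
#'   layout coordinates attached as attributes.
#' @export
sgrna_dataset <- function(df, window = 40L, spacer_len = 20L, name = "dataset") {
  stopifnot(is.data.frame(df), all(c("id", "sequence") %in% names(df)))
  df$id <- as.character(df$id)
  df$sequence <- toupper(as.character(df$sequence))
  if (anyDuplicated(df$id)) {
    stop("duplicate record ids: ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  probs <- vapply(df$sequence, function(s) {
    e <- validate_context(s, window, spacer_len)
    if (is.null(e)) "" else e
  }, character(1), USE.NAMES = FALSE)
  bad <- which(nzchar(probs))
  if (length(bad)) {
    stop("invalid records:\n", paste(sprintf("  %s: %s", df$id[bad], probs[bad]),
                                     collapse = "\n"))
  }
  if (!"label" %in% names(df)) df$label <- NA_integer_
  if (!all(is.na(df$label) | df$label %in% c(0, 1))) stop("label must be 0/1 or NA")
  df$label <- as.integer(df$label)
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  df$gene <- as.character(df$gene)
  coords <- locate_spacer(window, spacer_len)
  structure(df[, c("id", "sequence", "label", "gene")],
            window = as.integer(window), spacer_len = as.integer(spacer_len),
            spacer_start = unname(coords["spacer_start"]),
            spacer_end = unname(coords["spacer_end"]),
            pam_start = unname(coords["pam_start"]),
            name = name, class = c("sgrna_dataset", "data.frame"))
}

#' @export
print.sgrna_dataset <- function(x, ...) {
  cat(sprintf("<sgrna_dataset '%s'> %d records, %d bp window, %d nt spacer (%d-%d), PAM N at %d\n",
              attr(x, "name"), nrow(x), attr(x, "window"), attr(x, "spacer_len"),
              attr(x, "spacer_start"), attr(x, "spacer_end"), attr(x, "pam_start")))
  if (!all(is.na(x$label))) {
    cat(sprintf("  labels: %d efficient / %d inefficient\n",
                sum(x$label == 1, na.rm = TRUE), sum(x$label == 0, na.rm = TRUE)))
  }
  invisible(x)
}

#' Extract spacer sequences from a dataset
#' @param dataset an `sgrna_dataset`.
#' @return character vector of spacer substrings, one per record.
#' @export
spacers <- function(dataset) {
  substr(dataset$sequence, attr(dataset, "spacer_start"), attr(dataset, "spacer_end"))
}

#' Read sgRNA context records from a table or FASTA file
#'
#' Accepts TSV/CSV with header columns `id`, `sequence` and optional `label`,
#' `gene`, or a FASTA file plus a sidecar label table keyed by record id.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"tsv"`, `"csv"`, `"fasta"`; `"auto"` guesses
#'   from the extension.
#' @param labels for FASTA input, path to a TSV with columns `id`, `label` and
#'   optional `gene`.
#' @param window,spacer_len layout parameters (see [locate_spacer()]).
#' @param name dataset name; defaults to the file basename.
#' @return an `sgrna_dataset`.
#' @export
read_sgrna_table <- function(path, format = c("auto", "tsv", "csv", "fasta"),
                             labels = NULL, window = 40L, spacer_len = 20L,
                             name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", fa = "fasta", fasta = "fasta", fna = "fasta", "tsv")
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("FASTA input requires the Biostrings package")
    }
    seqs <- Biostrings::readDNAStringSet(path)
    df <- data.frame(id = sub("\\s.*$", "", names(seqs)),
                     sequence = as.character(seqs), stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      lab <- read.delim(labels, stringsAsFactors = FALSE)
      if (!all(c("id", "label") %in% names(lab))) {
        stop("label sidecar must have columns id, label")
      }
      df <- merge(df, lab, by = "id", all.x = TRUE, sort = FALSE)
    }
  } else {
    df <- read.delim(path, sep = if (format == "csv") "," else "\t",
                     stringsAsFactors = FALSE)
    if (!all(c("id", "sequence") %in% names(df))) {
      stop("input must have header columns id, sequence")
    }
  }
  sgrna_dataset(df, window = window, spacer_len = spacer_len,
                name = name %||% basename(path))
}

#' Write an sgRNA dataset back to TSV
#' @param dataset an `sgrna_dataset`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sgrna_table <- function(dataset, path) {
  write.table(as.data.frame(dataset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
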