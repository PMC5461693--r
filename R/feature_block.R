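FEATURE_CLASSES <- c("PDMono", "PDDinuc", "Freq", "Align", "Thermo", "Packer",
                     "PhyChem", "PseKNC")

feature_block <- function(class_name, values, feature_names, ids) {
  stopifnot(class_name %in% FEATURE_CLASSES,
            ncol(values) == length(feature_names),
            !anyDuplicated(feature_names))
  dimnames(values) <- list(ids, feature_names)
  structure(list(class_name = class_name, feature_names = feature_names,
                 values = values), class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block %s> %d records x %d features\n",
              x$class_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Column-bind feature blocks into a model matrix
#'
#' Feature names are prefixed with the class name so that joined matrices are
#' unambiguous (e.g. `Freq.freq_TT`).
#'
#' @param blocks list of `feature_block` objects over the same records.
#' @return numeric matrix, rows = records, columns = prefixed features.
#' @export
bind_feature_blocks <- function(blocks) {
  if (inherits(blocks, "feature_block")) blocks <- list(blocks)
  n <- unique(vapply(blocks, function(b) nrow(b$values), integer(1)))
  stopifnot(length(n) == 1)
  mats <- lapply(blocks, function(b) {
    m <- b$values
    colnames(m) <- paste(b$class_name, colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Compute feature blocks for a dataset
#'
#' Dispatches to the individual feature-class extractors. `Align`, `Packer`,
#' `PhyChem` and `PseKNC` accept options through `config`:
#' `align` (list: `match`, `mismatch`, `gap`, `scaffold`), `pseknc`
#' (list: `k`, `lambda`, `w`, `standardized`), `thermo`
#' (list: `na_molar`, `min_loop`, `max_loop`).
#'
#' @param dataset an `sgrna_dataset`.
#' @param classes character vector of class names (subset of
#'   `PDMono, PDDinuc, Freq, Align, Thermo, Packer, PhyChem, PseKNC`).
#' @param config optional named list of per-class options.
#' @return named list of `feature_block`s, in the order requested.
#' @export
feature_blocks <- function(dataset, classes = FEATURE_CLASSES, config = list()) {
  stopifnot(all(classes %in% FEATURE_CLASSES))
  out <- lapply(classes, function(cl) {
    switch(cl,
      PDMono = pd_mono(dataset),
      PDDinuc = pd_dinuc(dataset),
      Freq = freq_block(dataset),
      Align = do.call(align_block, c(list(dataset), config$align)),
      Thermo = do.call(thermo_block, c(list(dataset), config$thermo)),
      Packer = packer_block(dataset),
      PhyChem = phychem_block(dataset),
      PseKNC = do.call(pseknc_block, c(list(dataset), config$pseknc)))
  })
  names(out) <- classes
  out
}

#' Write a feature block (or bound matrix) as TSV
#' @param x a `feature_block` or numeric matrix with record rownames.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(x, path) {
  m <- if (inherits(x, "feature_block")) x$values else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
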