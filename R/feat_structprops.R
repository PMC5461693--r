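#' Summarize a property table over a spacer
#'
#' Looks up the score of every overlapping k-word of the spacer in the table
#' and returns the minimum, maximum and average.
#'
#' @param spacer DNA string with `nchar(spacer) >= k`.
#' @param table a `property_table`.
#' @return named numeric vector `c(min, max, avg)`.
#' @export
summarize_property <- function(spacer, table) {
  k <- table$k
  L <- nchar(spacer)
  if (L < k) stop("spacer shorter than word size k = ", k)
  words <- substring(spacer, 1:(L - k + 1L), k:L)
  s <- table$scores[words]
  if (anyNA(s)) stop("word(s) absent from property table '", table$name,
                     "': corrupted resource")
  c(min = min(s), max = max(s), avg = mean(s))
}

property_summary_block <- function(dataset, tables, class_name) {
  sp <- spacers(dataset)
  cols <- as.vector(vapply(names(tables), function(nm) paste(nm, c("min", "max", "avg"), sep = "_"),
                           character(3)))
  vals <- t(vapply(sp, function(s) {
    unlist(lapply(tables, summarize_property, spacer = s), use.names = FALSE)
  }, numeric(length(cols)), USE.NAMES = FALSE))
  feature_block(class_name, vals, cols, dataset$id)
}

#' Structural geometry and deformability feature class (Packer)
#'
#' Min/max/avg summaries of four dinucleotide geometry scales (roll, twist,
#' slide, shift) and two tetranucleotide scales (energy, flexibility) over
#' the spacer; 6 tables x 3 statistics = 18 columns. The shipped tables are
#' synthetic representative scales (see their file headers).
#'
#' @param dataset an `sgrna_dataset`.
#' @param tables named list of 6 `property_table`s; defaults to the shipped set.
#' @return a `feature_block` with 18 columns.
#' @export
packer_block <- function(dataset, tables = load_property_group("packer")) {
  stopifnot(length(tables) == 6)
  property_summary_block(dataset, tables, "Packer")
}

#' Physiochemical property feature class (PhyChem)
#'
#' Min/max/avg summaries of 12 dinucleotide physiochemical scales
#' (A-philicity, base stacking, B-DNA twist, bendability, bending stiffness,
#' denaturation, duplex disrupt energy, duplex free energy, propeller twist,
#' protein deformation, protein-DNA twist, Z-DNA) over the spacer;
#' 12 x 3 = 36 columns. The shipped tables are synthetic representative
#' scales (see their file headers).
#'
#' @param dataset an `sgrna_dataset`.
#' @param tables named list of 12 dinucleotide `property_table`s.
#' @return a `feature_block` with 36 columns.
#' @export
phychem_block <- function(dataset, tables = load_property_group("phychem")) {
  stopifnot(length(tables) == 12)
  property_summary_block(dataset, tables, "PhyChem")
}
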