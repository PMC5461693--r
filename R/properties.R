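#' Load a word-score property table
#'
#' Property tables are plain-text resources (`word<TAB>score`, `#` comment
#' header) shipped under `inst/extdata/property_tables`. A table must be total
#' over its alphabet: 16 entries for dinucleotides (k = 2) or 256 for
#' tetranucleotides (k = 4).
#'
#' @param file path to a table, or the bare name of a shipped resource
#'   (with or without the `.tsv` extension).
#' @return a `property_table`: list with `name`, `k`, `scores` (named numeric
#'   vector in alphabetical word order) and `source`.
#' @export
load_property_table <- function(file) {
  path <- resolve_resource(file)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t")
  words <- vapply(parts, `[`, character(1), 1L)
  scores <- as.numeric(vapply(parts, `[`, character(1), 2L))
  k <- unique(nchar(words))
  if (length(k) != 1 || !k %in% c(2L, 4L)) {
    stop("property table must contain words of a single length 2 or 4: ", path)
  }
  expect <- sort(apply(do.call(expand.grid, rep(list(BASES), k)), 1, paste,
                       collapse = ""))
  if (anyDuplicated(words) || !setequal(words, expect) || anyNA(scores)) {
    stop(sprintf("corrupted property table %s: need all %d %d-mers exactly once with numeric scores",
                 path, 4^k, k))
  }
  nm <- sub("^# property: *", "", grep("^# property:", hdr, value = TRUE)[1])
  if (is.na(nm)) nm <- sub("\\.tsv$", "", basename(path))
  structure(list(name = nm, k = as.integer(k),
                 scores = setNames(scores, words)[expect],
                 source = paste(sub("^# *", "", hdr), collapse = " ")),
            class = "property_table")
}

resolve_resource <- function(file) {
  if (file.exists(file)) return(file)
  base <- if (grepl("\\.tsv$", file)) file else paste0(file, ".tsv")
  path <- system.file("extdata", "property_tables", base, package = "sgdesign")
  if (!nzchar(path)) stop("property table not found: ", file)
  path
}

#' Load the nearest-neighbor duplex parameter set
#'
#' Unified nearest-neighbor parameters for DNA duplex formation: per
#' dinucleotide step dH (kcal/mol), dS (cal/(mol.K)) and dG at 37 C
#' (kcal/mol), plus initiation terms for terminal G.C and A.T pairs and the
#' symmetry correction for self-complementary duplexes. Loading verifies that
#' all 16 steps are present and that dG37 = dH - 310.15 dS / 1000 holds within
#' 0.05 kcal/mol for every entry.
#'
#' @param file resource path; defaults to the shipped table.
#' @return an `nn_params` list with matrices/vectors `steps` (16 x 3),
#'   `init_GC`, `init_AT`, `symmetry`.
#' @export
load_nn_params <- function(file = "nn_duplex") {
  path <- resolve_resource(file)
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  parts <- do.call(rbind, strsplit(lines, "\t"))
  keys <- parts[, 1]
  vals <- matrix(as.numeric(parts[, 2:4]), ncol = 3,
                 dimnames = list(keys, c("dH", "dS", "dG")))
  need <- c(DINUCS, "init_GC", "init_AT", "symmetry")
  if (!setequal(keys, need)) stop("NN parameter file must define all 16 steps, init_GC, init_AT, symmetry")
  dev <- abs(vals[, "dG"] - (vals[, "dH"] - 310.15 * vals[, "dS"] / 1000))
  if (any(dev > 0.05)) {
    stop("NN parameter inconsistency: dG37 != dH - 310.15*dS/1000 for ",
         paste(rownames(vals)[dev > 0.05], collapse = ", "))
  }
  # use dG37 derived from dH/dS so sums over many steps stay exactly
  # consistent; the printed dG column serves as the per-step sanity check above
  vals[, "dG"] <- vals[, "dH"] - 310.15 * vals[, "dS"] / 1000
  structure(list(steps = vals[DINUCS, , drop = FALSE],
                 init_GC = vals["init_GC", ], init_AT = vals["init_AT", ],
                 symmetry = vals["symmetry", ]),
            class = "nn_params")
}

packer_table_names <- function() {
  c("synthetic_packer_roll", "synthetic_packer_twist", "synthetic_packer_slide",
    "synthetic_packer_shift", "synthetic_tetra_energy", "synthetic_tetra_flexibility")
}

phychem_table_names <- function() {
  paste0("synthetic_phychem_",
         c("a_philicity", "base_stacking", "b_dna_twist", "bendability",
           "bending_stiffness", "denaturation", "duplex_disrupt_energy",
           "duplex_free_energy", "propeller_twist", "protein_deformation",
           "protein_dna_twist", "z_dna"))
}

pseknc_table_names <- function() {
  paste0("synthetic_pseknc_", c("rise", "slide", "shift", "twist", "roll", "tilt"))
}

#' Load a standard group of property tables
#' @param group `"packer"` (4 dinucleotide geometry + 2 tetranucleotide
#'   scales), `"phychem"` (12 dinucleotide physiochemical scales) or
#'   `"pseknc"` (6 local translational/angular scales).
#' @return named list of `property_table` objects.
#' @export
load_property_group <- function(group = c("packer", "phychem", "pseknc")) {
  group <- match.arg(group)
  if (!is.null(.sg_cache[[group]])) return(.sg_cache[[group]])
  files <- switch(group, packer = packer_table_names(),
                  phychem = phychem_table_names(), pseknc = pseknc_table_names())
  tabs <- lapply(files, load_property_table)
  names(tabs) <- vapply(tabs, `[[`, character(1), "name")
  .sg_cache[[group]] <- tabs
  tabs
}

.sg_cache <- new.env(parent = emptyenv())

# alphabetical k-mer vocabulary, memoized
kmer_words <- function(k) {
  key <- paste0("kmers", k)
  if (is.null(.sg_cache[[key]])) {
    .sg_cache[[key]] <- sort(apply(do.call(expand.grid, rep(list(BASES), k)),
                                   1, paste, collapse = ""))
  }
  .sg_cache[[key]]
}

#' Load the default sgRNA scaffold sequence
#'
#' Returns the shipped SpCas9 scaffold (DNA alphabet) unless another FASTA is
#' given. Any `U` characters are mapped to `T` on load.
#'
#' @param file FASTA file; default is the packaged scaffold.
#' @return a single DNA string.
#' @export
load_scaffold <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "scaffold_spcas9.fa", package = "sgdesign")
  }
  lines <- readLines(file)
  seq <- toupper(paste(grep("^>", lines, value = TRUE, invert = TRUE), collapse = ""))
  seq <- chartr("U", "T", seq)
  if (!nzchar(seq) || grepl("[^ACGT]", seq)) stop("scaffold must be a nonempty A/C/G/T(/U) sequence")
  seq
}
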