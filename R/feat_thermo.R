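#' Oligonucleotide melting temperature
#'
#' Salt-adjusted GC-fraction formula:
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 (%GC) - 600/L`, with %GC on the
#' 0-100 scale and L the sequence length.
#'
#' @param spacer DNA string.
#' @param na_molar sodium concentration in mol/L (default 0.2 M).
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature(strrep("AC", 10))  # 50% GC 20-mer: 60.40 C
melting_temperature <- function(spacer, na_molar = 0.2) {
  L <- nchar(spacer)
  if (is.na(spacer) || L == 0) stop("empty sequence")
  if (na_molar <= 0) stop("na_molar must be positive")
  gc <- gc_fraction(spacer)
  81.5 + 16.6 * log10(na_molar) + 0.41 * (100 * gc) - 600 / L
}

gc_fraction <- function(spacer) {
  ch <- strsplit(spacer, "")[[1]]
  mean(ch %in% c("G", "C"))
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Sums the per-step enthalpy, entropy and free-energy parameters over the
#' L-1 overlapping dinucleotide steps, adds both terminal initiation terms
#' (G.C vs A.T depending on the terminal base pair) and the symmetry
#' correction when the sequence is self-complementary.
#'
#' @param spacer DNA string, length >= 2.
#' @param params an `nn_params` set from [load_nn_params()].
#' @return named numeric vector `c(dH, dS, dG)` in kcal/mol, cal/(mol.K),
#'   kcal/mol.
#' @export
nn_thermo <- function(spacer, params = load_nn_params()) {
  L <- nchar(spacer)
  if (L < 2) stop("need at least 2 nt")
  steps <- substring(spacer, 1:(L - 1), 2:L)
  tot <- colSums(params$steps[steps, , drop = FALSE])
  for (end in c(substr(spacer, 1, 1), substr(spacer, L, L))) {
    tot <- tot + if (end %in% c("G", "C")) params$init_GC else params$init_AT
  }
  if (spacer == revcomp(spacer)) tot <- tot + params$symmetry
  tot
}

#' Longest homopolymer run
#' @param spacer DNA string.
#' @return integer length of the longest single-base run (>= 1).
#' @export
poly_n <- function(spacer) {
  if (nchar(spacer) == 0) stop("empty sequence")
  max(rle(strsplit(spacer, "")[[1]])$lengths)
}

#' Longest repeated substring
#'
#' Length of the longest substring occurring at two or more distinct
#' (possibly overlapping) start positions; 0 when no repetition exists.
#'
#' @param spacer DNA string.
#' @return integer.
#' @export
longest_repeat <- function(spacer) {
  L <- nchar(spacer)
  if (L < 2) return(0L)
  for (len in (L - 1L):1L) {
    subs <- substring(spacer, 1:(L - len + 1L), len:L)
    if (anyDuplicated(subs)) return(len)
  }
  0L
}

#' Longest stem-loop arm (LSL)
#'
#' Maximum arm length `a` for which the sequence contains a perfect inverted
#' repeat: an arm of `a` bases followed, after a loop gap of `min_loop` to
#' `max_loop` unpaired bases, by its reverse complement. Returns 0 when no
#' such placement exists.
#'
#' @param spacer DNA string.
#' @param min_loop,max_loop allowed loop gap in bases.
#' @return integer arm length.
#' @export
longest_stem_loop <- function(spacer, min_loop = 3L, max_loop = 10L) {
  L <- nchar(spacer)
  best <- 0L
  a <- 1L
  while (2L * a + min_loop <= L) {
    found <- FALSE
    for (i in 1:(L - 2L * a - min_loop + 1L)) {
      arm <- substr(spacer, i, i + a - 1L)
      rc <- revcomp(arm)
      for (g in min_loop:min(max_loop, L - i + 1L - 2L * a)) {
        j <- i + a + g
        if (substr(spacer, j, j + a - 1L) == rc) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
    best <- a
    a <- a + 1L
  }
  best
}

#' Minimum energy folding (MEF)
#'
#' Minimum free energy over all pseudoknot-free secondary structures of the
#' sequence under a simplified stacking model: Watson-Crick pairs only,
#' minimum hairpin loop of 3 unpaired bases, energy = sum of nearest-neighbor
#' dG37 over stacked adjacent pairs plus a fixed penalty per hairpin loop.
#' The unstructured sequence scores 0, so the result is always <= 0. This is
#' a deliberately small Zuker-style folder, not a full loop-based energy
#' model.
#'
#' @param spacer DNA string, length >= 5 for any structure to be possible.
#' @param params an `nn_params` set (stacking dG37 values are used).
#' @param hairpin_penalty destabilizing cost per hairpin loop, kcal/mol.
#' @param min_hairpin minimum unpaired bases closed by a hairpin pair.
#' @return minimum folding energy in kcal/mol (<= 0).
#' @export
minimum_energy_folding <- function(spacer, params = load_nn_params(),
                                   hairpin_penalty = 3.5, min_hairpin = 3L) {
  L <- nchar(spacer)
  ch <- strsplit(spacer, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairable <- function(i, j) ch[j] == comp[[ch[i]]]
  dG <- params$steps[, "dG"]
  if (L < 2L * 1L + min_hairpin) return(0)
  V <- matrix(Inf, L, L)   # min energy with (i,j) paired
  Wne <- matrix(Inf, L, L) # min energy over nonempty structures on [i,j]
  for (span in (min_hairpin + 1L):(L - 1L)) {
    for (i in 1:(L - span)) {
      j <- i + span
      if (pairable(i, j)) {
        v <- hairpin_penalty
        if (j - i - 1L > min_hairpin + 1L && pairable(i + 1L, j - 1L) &&
            is.finite(V[i + 1L, j - 1L])) {
          v <- min(v, dG[[paste0(ch[i], ch[i + 1L])]] + V[i + 1L, j - 1L])
        }
        if (j - 1L > i + 1L && is.finite(Wne[i + 1L, j - 1L])) {
          v <- min(v, Wne[i + 1L, j - 1L])
        }
        V[i, j] <- v
      }
      w <- if (j - 1L >= i + 1L) Wne[i + 1L, j] else Inf
      for (k in (i + min_hairpin + 1L):j) {
        if (is.finite(V[i, k])) {
          rest <- if (k + 1L <= j) min(0, Wne[k + 1L, j]) else 0
          w <- min(w, V[i, k] + rest)
        }
      }
      Wne[i, j] <- w
    }
  }
  min(0, Wne[1, L])
}

#' Thermodynamic and secondary-structure feature class (Thermo)
#'
#' Nine spacer-level scalars: melting temperature, GC fraction, duplex dS, dH
#' and dG, longest homopolymer run (polyN), longest repeated substring
#' (repeat), longest stem-loop arm (LSL), and minimum folding energy (MEF).
#'
#' @param dataset an `sgrna_dataset`.
#' @param na_molar sodium concentration for Tm.
#' @param min_loop,max_loop stem-loop search window.
#' @param params nearest-neighbor parameter set.
#' @return a `feature_block` with 9 columns.
#' @export
thermo_block <- function(dataset, na_molar = 0.2, min_loop = 3L, max_loop = 10L,
                         params = load_nn_params()) {
  sp <- spacers(dataset)
  vals <- t(vapply(sp, function(s) {
    nt <- nn_thermo(s, params)
    c(Tm = melting_temperature(s, na_molar), GC = gc_fraction(s),
      dS = unname(nt["dS"]), dH = unname(nt["dH"]), dG = unname(nt["dG"]),
      polyN = poly_n(s), repeat_len = longest_repeat(s),
      LSL = longest_stem_loop(s, min_loop, max_loop),
      MEF = minimum_energy_folding(s, params))
  }, numeric(9), USE.NAMES = FALSE))
  feature_block("Thermo", vals,
                c("Tm", "GC", "dS", "dH", "dG", "polyN", "repeat", "LSL", "MEF"),
                dataset$id)
}
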