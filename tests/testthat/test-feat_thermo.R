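params <- load_nn_params()

test_that("melting temperature evaluates the salt-adjusted formula", {
  expect_equal(melting_temperature(strrep("AC", 10), 0.2), 60.40, tolerance = 1e-3)
  expect_equal(melting_temperature(strrep("A", 20), 0.2), 39.90, tolerance = 1e-3)
  # +10% GC on a 20-mer adds exactly 4.1 C
  expect_equal(melting_temperature(paste0(strrep("G", 12), strrep("A", 8))) -
                 melting_temperature(paste0(strrep("G", 10), strrep("A", 10))),
               0.41 * 10)
  # strictly increasing in salt
  expect_gt(melting_temperature(strrep("AC", 10), 0.5),
            melting_temperature(strrep("AC", 10), 0.2))
  expect_error(melting_temperature(""), "empty")
})

test_that("nearest-neighbor sums include initiation and symmetry terms", {
  # hand sum for ACGT (self-complementary): steps AC, CG, GT; both terminal
  # pairs are A.T, so the A.T initiation term applies twice
  hand <- colSums(params$steps[c("AC", "CG", "GT"), ]) +
    2 * params$init_AT + params$symmetry
  expect_equal(nn_thermo("ACGT", params), hand)
  # ACGA is not self-complementary: no symmetry term
  hand2 <- colSums(params$steps[c("AC", "CG", "GA"), ]) + 2 * params$init_AT
  expect_equal(nn_thermo("ACGA", params), hand2)
})

nn_thermo_no_sym <- function(s) {
  L <- nchar(s)
  tot <- colSums(params$steps[substring(s, 1:(L - 1), 2:L), , drop = FALSE])
  for (end in c(substr(s, 1, 1), substr(s, L, L))) {
    tot <- tot + if (end %in% c("G", "C")) params$init_GC else params$init_AT
  }
  tot
}

test_that("dG/dH/dS are mutually consistent on random 20-mers", {
  set.seed(11)
  for (s in random_dna(50, 20)) {
    v <- nn_thermo(s, params)
    expect_lt(abs(v["dG"] - (v["dH"] - 310.15 * v["dS"] / 1000)), 0.1)
    expect_equal(s == revcomp(s),
                 isTRUE(all.equal(v, nn_thermo_no_sym(s) + params$symmetry)))
  }
})

test_that("polyN and longest repeat match their definitions", {
  expect_equal(poly_n("AAACCCCGT"), 4)
  expect_equal(poly_n("A"), 1)
  expect_equal(longest_repeat("A"), 0)
  # brute-force check: longest substring with >= 2 distinct starts
  bf_rep <- function(s) {
    L <- nchar(s)
    best <- 0
    for (len in 1:(L - 1)) {
      subs <- substring(s, 1:(L - len + 1), len:L)
      if (anyDuplicated(subs)) best <- len
    }
    best
  }
  expect_equal(longest_repeat("ACGTACGTAA"), bf_rep("ACGTACGTAA"))
  expect_equal(longest_repeat("ACGTACGTAA"), 5)  # "ACGTA" at starts 1 and 5
  set.seed(12)
  for (s in random_dna(30, 12)) expect_equal(longest_repeat(s), bf_rep(s))
})

test_that("stem-loop arm equals exhaustive placement search", {
  expect_equal(longest_stem_loop(strrep("A", 20)), 0)
  expect_equal(longest_stem_loop("GCGCAAAAGCGC"), bf_lsl("GCGCAAAAGCGC"))
  set.seed(13)
  for (s in random_dna(40, 20)) {
    expect_equal(longest_stem_loop(s), bf_lsl(s))
    expect_equal(longest_stem_loop(revcomp(s)), longest_stem_loop(s))
  }
})

test_that("MEF dynamic program equals exhaustive structure enumeration", {
  expect_equal(minimum_energy_folding(strrep("A", 20), params), 0)
  set.seed(14)
  for (s in random_dna(25, sample(8:12, 25, replace = TRUE))) {
    expect_equal(minimum_energy_folding(s, params), bf_mef(s, params),
                 info = s)
  }
})

test_that("appending a perfect inverted repeat never raises MEF", {
  set.seed(15)
  for (core in random_dna(10, 8)) {
    arm <- "GCGCGC"
    ext <- paste0(arm, "AAAA", revcomp(arm), core)
    expect_lte(minimum_energy_folding(ext, params),
               minimum_energy_folding(core, params))
  }
})

test_that("Thermo block has 9 named scalars and depends only on the spacer", {
  sp <- "ACGTACGTTTACGGATCCAT"
  ds <- tiny_dataset(c(sp, sp), )
  ds$id <- c("a", "b")  # same spacer, same features
  blk <- thermo_block(ds)
  expect_equal(colnames(blk$values),
               c("Tm", "GC", "dS", "dH", "dG", "polyN", "repeat", "LSL", "MEF"))
  expect_equal(blk$values[1, ], blk$values[2, ])
  expect_true(blk$values[1, "MEF"] <= 0)
  expect_gte(blk$values[1, "polyN"], 1)
  expect_equal(unname(blk$values[1, "Tm"]), melting_temperature(sp))
})
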