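mkfp <- function(bits, version = "v1", name = "x") {
  structure(list(name = name, version = version, bits = as.integer(bits)),
            class = "xr_fingerprint")
}

test_that("key dictionary is dense, versioned and validated", {
  d <- load_key_dictionary("v1")
  expect_equal(nrow(d), 166)
  expect_identical(d$key, 1:166)
  expect_true(all(d$min_count >= 1))
  expect_error(load_key_dictionary("no-such-version"), "no packaged")
})

test_that("methane sets no ring, aromatic or heteroatom-pair keys", {
  fp <- compute_fingerprint(standardize_compound(compound("C", "methane")))
  # 162 aromatic atom, 163 six-ring, 165 ring atom, 124 heteroatom~heteroatom
  expect_equal(fp$bits[c(124, 162, 163, 165)], c(0L, 0L, 0L, 0L))
  expect_lt(sum(fp$bits), 5)
})

test_that("cortisol sets carbonyl and hydroxyl keys", {
  fpm <- panel_fingerprints()
  expect_equal(unname(fpm["cortisol", 154]), 1L)  # [#6]=[#8]
  expect_equal(unname(fpm["cortisol", 139]), 1L)  # [O;!H0]
  expect_equal(unname(fpm["cortisol", 163]), 1L)  # six-membered ring
})

test_that("stereoisomers receive identical fingerprints and similarity 1", {
  fpm <- panel_fingerprints()
  expect_identical(fpm["pregnanolone", ], fpm["allopregnanolone", ])
  expect_equal(panel_similarity("pregnanolone", "allopregnanolone"), 1)
  expect_identical(fpm["5beta-dihydroprogesterone", ],
                   fpm["5alpha-pregnan-3,20-dione", ])
})

test_that("fingerprinting requires a standardized compound", {
  expect_error(compute_fingerprint(compound("CCO", "ethanol")), "standardized")
})

test_that("the multi-aromatic-ring and fragment keys are computed, not matched", {
  biphenyl <- compute_fingerprint(standardize_compound(
    compound("c1ccc(cc1)-c1ccccc1", "biphenyl")))
  expect_equal(biphenyl$bits[125], 1L)
  estradiol <- panel_fingerprints()["estradiol", ]
  expect_equal(estradiol[[125]], 0L)  # single aromatic ring
  # standardized structures are single-fragment, so key 166 is always clear
  expect_equal(biphenyl$bits[166], 0L)
})

test_that("tanimoto follows the set algebra", {
  a <- mkfp(c(1, 1, 1, 1, 1, 0, 0, 0))
  b <- mkfp(c(1, 1, 1, 0, 0, 1, 0, 0))
  expect_equal(tanimoto(a, b), 3 / 6)  # |a|=5, |b|=4, shared=3
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(mkfp(c(1, 0)), mkfp(c(0, 1))), 0)
  expect_message(v <- tanimoto(mkfp(c(0, 0)), mkfp(c(0, 0))), "empty")
  expect_equal(v, 1)
  expect_equal(suppressMessages(tanimoto(mkfp(c(0, 0)), mkfp(c(1, 0)))), 0)
})

test_that("tanimoto refuses mismatched dictionary versions", {
  expect_error(tanimoto(mkfp(c(1, 0), version = "v1"),
                        mkfp(c(1, 0), version = "v2")), "version mismatch")
})

test_that("tanimoto is symmetric and bounded on all panel pairs", {
  fpm <- panel_fingerprints()
  n <- nrow(fpm)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- tanimoto(fpm[i, ], fpm[j, ])
      expect_gte(s, 0); expect_lte(s, 1)
      expect_identical(s, tanimoto(fpm[j, ], fpm[i, ]))
    }
  }
})

test_that("tanimoto matches a brute-force set-intersection oracle on random vectors", {
  set.seed(166)
  for (k in seq_len(1000)) {
    a <- stats::rbinom(166, 1, runif(1, 0.05, 0.6))
    b <- stats::rbinom(166, 1, runif(1, 0.05, 0.6))
    expect_identical(tanimoto(mkfp(a), mkfp(b)), tanimoto_set_oracle(a, b))
  }
})

test_that("fingerprints agree with an independent public-keys implementation", {
  ref_path <- system.file("extdata", "public_keys_reference_fingerprints.tsv",
                          package = "crossreact")
  lines <- readLines(ref_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  fpm <- panel_fingerprints()
  agree <- vapply(parts, function(p) {
    ref <- fp_from_hex(p[2], name = p[1])
    mean(fpm[p[1], ] == ref$bits)
  }, numeric(1))
  expect_length(agree, nrow(fpm))
  expect_true(all(agree >= 0.95))
})

test_that("hex encoding round-trips fingerprints", {
  fpm <- panel_fingerprints()
  fp <- compute_fingerprint(panel_library()[["cortisol"]])
  expect_identical(fp_from_hex(fp_hex(fp), name = "cortisol")$bits, fp$bits)
})

test_that("similarity_panel is ordered, complete and handles empty input", {
  lib <- panel_library()
  sc <- similarity_panel(list(lib[["estradiol"]]),
                         lib[c("estrone", "estriol", "estradiol")])
  expect_equal(nrow(sc), 3)
  expect_equal(sc$query_name, c("estrone", "estriol", "estradiol"))
  expect_equal(sc$tanimoto[3], 1)  # candidate equal to target
  expect_equal(nrow(similarity_panel(list(lib[["estradiol"]]), list())), 0)
})
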