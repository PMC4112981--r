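# shared fixtures, computed once per test run
.helper_cache <- new.env()

panel_library <- function() {
  if (is.null(.helper_cache$lib))
    .helper_cache$lib <- load_compound_library()
  .helper_cache$lib
}

panel_fingerprints <- function() {
  if (is.null(.helper_cache$fpm))
    .helper_cache$fpm <- fingerprint_matrix(panel_library())
  .helper_cache$fpm
}

panel_similarity <- function(a, b) {
  fpm <- panel_fingerprints()
  tanimoto(fpm[a, ], fpm[b, ])
}

# brute-force Tanimoto over set indices, independent of the bit arithmetic
tanimoto_set_oracle <- function(a, b) {
  sa <- which(a != 0); sb <- which(b != 0)
  if (length(sa) == 0 && length(sb) == 0) return(1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# rebuild spiked measurements consistent with given CR values (exact inversion)
measurements_from_cr <- function(assay, compounds, cr_pct, spike, baseline = 10) {
  data.frame(assay = assay, compound = compounds, spike_ng_ml = spike,
             apparent_spiked_ng_ml = baseline + cr_pct / 100 * spike,
             apparent_baseline_ng_ml = baseline, stringsAsFactors = FALSE)
}
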