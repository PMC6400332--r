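# Shared phantom fixtures. Small grids keep the suite fast; 96x96 in-plane
# (divisible by 32) is the desk-scale stand-in for clinical 512x512.

small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(ct_shape = c(12L, 96L, 96L), ct_spacing = c(5, 2.7, 2.7),
                 seed = seed, ...)
}

# ten central bladder slices (cross-section comfortably above the networks'
# output stride) from two phantom patients; the standard capacity fixture
capacity_fixture <- function(min_fg = 150L) {
  c1 <- generate_phantom(small_phantom_config(seed = 1L), "P001")
  c2 <- generate_phantom(small_phantom_config(
    seed = 9L, bladder_center = c(0.5, 0.45, 0.55)), "P002")
  prs <- c(make_labels(c1$pet, c1$ct), make_labels(c2$pet, c2$ct))
  prs <- Filter(function(p) sum(p$mask) >= min_fg, prs)
  stopifnot(length(prs) >= 10L)
  prs[seq_len(10L)]
}

random_pairs <- function(n, nr = 24L, nc = 24L, n_patients = 3L) {
  lapply(seq_len(n), function(i) {
    slice_pair(matrix(round(rnorm(nr * nc, 50, 20)), nr, nc),
               random_mask(nr, nc, 0.2),
               patient_id = sprintf("P%02d", (i %% n_patients) + 1L),
               slice_index = i)
  })
}
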