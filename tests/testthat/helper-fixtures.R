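# Shared fixtures built in code.

hcline31_path <- function() {
  system.file("extdata", "hcline31_insertions.tsv", package = "onsenfate")
}

# tiny dosage matrix with named ecotypes/SNPs
tiny_panel <- function(dos, groups = NULL, aridity = NULL) {
  genotype_panel(dos, groups = groups, aridity = aridity)
}

# disc-assay table: k vital and k necrotic discs per image, reps per k
disc_assay_table <- function(ks = 1:3, reps = 3, noise_rate = 0,
                             seed_base = 100) {
  rows <- list()
  for (k in ks) {
    for (r in seq_len(reps)) {
      im <- synth_segmentation_image(k, k, seed = seed_base + 10 * k + r,
                                     noise_rate = noise_rate)
      cc <- count_class_pixels(im$image)
      rows[[length(rows) + 1]] <- tibble::tibble(
        class = c("vital", "necrotic"), n_discs = k,
        pixels = cc$pixels[match(c("vital", "necrotic"), cc$class)])
    }
  }
  dplyr::bind_rows(rows)
}
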