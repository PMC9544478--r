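#' Synthetic segmentation label image with known class areas
#'
#' Renders a disc-assay style label image: `k_vital` and `k_necrotic`
#' non-overlapping discs plus one rectangular scale-label patch on a
#' background grid. Disc centres are drawn (rejection sampling, deterministic
#' under `seed`) in normalised coordinates, so the same seed rendered at a
#' different `zoom` produces the same layout with all pixel counts scaled by
#' `zoom^2` (up to rasterisation). Optional class-flip noise swaps vital and
#' necrotic labels pixel-wise, mimicking classifier confusion between the
#' two leaf classes.
#'
#' @param k_vital,k_necrotic Number of discs per class (0-3 in the assay).
#' @param seed RNG seed (required: generators are deterministic).
#' @param size Base image side length in pixels.
#' @param disc_radius Disc radius in base pixels.
#' @param label_size Width/height of the scale-label patch in base pixels.
#' @param zoom Rendering zoom factor.
#' @param noise_rate Probability that a leaf pixel flips to the other leaf
#'   class.
#' @param max_tries Rejection-sampling budget for disc placement.
#' @return A list: `image` (integer label matrix) and `truth` (painted pixel
#'   counts per class after noise, single-disc rasterised area, disc centres).
#' @examples
#' synth_segmentation_image(1, 0, seed = 1)$truth$pixels
#' @export
synth_segmentation_image <- function(k_vital, k_necrotic, seed,
                                     size = 200, disc_radius = 15,
                                     label_size = c(20, 30), zoom = 1,
                                     noise_rate = 0, max_tries = 200) {
  stopifnot(k_vital >= 0, k_necrotic >= 0, noise_rate >= 0, noise_rate <= 1)
  set.seed(seed)
  n_discs <- k_vital + k_necrotic
  r_norm <- disc_radius / size
  lab_norm <- label_size / size
  # label patch fixed at the top-left corner with a small margin
  lab_x <- c(0.02, 0.02 + lab_norm[1])
  lab_y <- c(0.02, 0.02 + lab_norm[2])
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centres) < n_discs) {
    tries <- tries + 1
    if (tries > max_tries * max(1, n_discs)) {
      abort("Could not place all discs without overlap within the retry budget.")
    }
    cand <- runif(2, min = r_norm + 0.01, max = 1 - r_norm - 0.01)
    in_label <- cand[1] > lab_x[1] - r_norm && cand[1] < lab_x[2] + r_norm &&
      cand[2] > lab_y[1] - r_norm && cand[2] < lab_y[2] + r_norm
    if (in_label) next
    if (nrow(centres) > 0) {
      d2 <- (centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2
      if (any(d2 < (2 * r_norm + 0.01)^2)) next
    }
    centres <- rbind(centres, cand)
  }
  px <- round(size * zoom)
  img <- matrix(0L, px, px)
  xg <- (col(img) - 0.5) / px # x = column, y = row, normalised
  yg <- (row(img) - 0.5) / px
  img[xg >= lab_x[1] & xg < lab_x[2] & yg >= lab_y[1] & yg < lab_y[2]] <-
    pixel_classes[["scale_label"]]
  classes <- rep(c(pixel_classes[["vital"]], pixel_classes[["necrotic"]]),
                 c(k_vital, k_necrotic))
  disc_pixels <- integer(n_discs)
  for (i in seq_len(n_discs)) {
    inside <- (xg - centres[i, 1])^2 + (yg - centres[i, 2])^2 <= r_norm^2
    disc_pixels[i] <- sum(inside)
    img[inside] <- classes[i]
  }
  n_flipped <- 0L
  if (noise_rate > 0) {
    leaf <- which(img == 1L | img == 2L)
    flip <- leaf[runif(length(leaf)) < noise_rate]
    img[flip] <- 3L - img[flip] # 1 <-> 2
    n_flipped <- length(flip)
  }
  counts <- tabulate(as.integer(img) + 1L, nbins = 4L)
  # single-disc reference area at this zoom (centre-of-frame rasterisation)
  ref_inside <- (xg - 0.5)^2 + (yg - 0.5)^2 <= r_norm^2
  list(image = img,
       truth = list(
         pixels = setNames(counts, names(pixel_classes)),
         disc_pixels = disc_pixels,
         single_disc_area = sum(ref_inside),
         label_pixels = counts[4],
         centres = centres, n_flipped = n_flipped,
         k_vital = k_vital, k_necrotic = k_necrotic, zoom = zoom))
}

#' Synthetic pot-weight series with size-dependent evaporation
#'
#' Emulates the drought-assay weighing record: each pot starts at a saturated
#' weight and loses `a + b * size + N(0, sigma)` grams per day (larger plants
#' transpire more). Weights never cross the pot's dry weight; truncated days
#' are flagged.
#'
#' @param sizes Per-pot plant sizes (vital pixel counts or any size proxy).
#' @param seed RNG seed.
#' @param days Measurement days (day 0 = saturation).
#' @param a Baseline evaporation (g/day), `b` size coefficient, `sigma`
#'   daily noise SD.
#' @param b,sigma See `a`.
#' @param saturated_weight,dry_weight Common initial and dry pot weights (g).
#' @param lines Optional per-pot line labels (recycled), recorded in the
#'   output for water-model fits.
#' @return A list: `weights` tibble (`pot`, `line`, `size`, `day`,
#'   `weight_g`, `dry_weight_g`, `truncated`) and `truth`
#'   (`a`, `b`, `sigma`, per-day slope identity `cumulative_slope(day) =
#'   day * b`).
#' @export
synth_weight_series <- function(sizes, seed, days = c(1, 8, 15, 22, 27),
                                a = 5, b = 0.004, sigma = 1,
                                saturated_weight = 320, dry_weight = 100,
                                lines = "line1") {
  stopifnot(all(sizes > 0))
  set.seed(seed)
  n <- length(sizes)
  lines <- rep_len(lines, n)
  pots <- sprintf("pot%03d", seq_len(n))
  all_days <- seq_len(max(days))
  nd <- length(all_days)
  # daily losses as a days x pots matrix; weights decrease cumulatively
  loss <- matrix(rep(a + b * sizes, each = nd) + rnorm(nd * n, 0, sigma),
                 nrow = nd)
  w <- saturated_weight - apply(loss, 2, cumsum)
  truncated <- w < dry_weight
  w[truncated] <- dry_weight
  weights <- tibble::tibble(
    pot = rep(pots, each = length(days)),
    line = rep(lines, each = length(days)),
    size = rep(sizes, each = length(days)),
    day = rep(days, n),
    weight_g = as.vector(w[days, ]),
    dry_weight_g = dry_weight,
    truncated = as.vector(truncated[days, ]))
  list(weights = weights,
       truth = list(a = a, b = b, sigma = sigma,
                    saturated_weight = saturated_weight,
                    dry_weight = dry_weight,
                    cumulative_slope = function(day) day * b))
}

#' Synthetic TIP catalogue in the printed table style
#'
#' Draws insertion records with an exon-biased context distribution (ONSEN
#' inserts preferentially into actively transcribed regions) and Bernoulli
#' zygosity, and can render them to a TSV in the abbreviated-coordinate
#' style parsed by [read_insertion_table()].
#'
#' @param n Number of insertions.
#' @param seed RNG seed.
#' @param exon_bias Probability that a record's context is `Exon`; the
#'   remainder splits evenly across `Intron`, `Promoter`, `TE`.
#' @param hom_prob Probability that a record is homozygous.
#' @param path Optional TSV output path (written via
#'   [write_insertion_table()]).
#' @return A list: `records` tibble (the [read_insertion_table()] schema)
#'   and `truth` (`n_exon`, `n_hom`, `n_candidates` = exonic homozygous
#'   count).
#' @export
synth_tip_table <- function(n, seed, exon_bias = 0.6, hom_prob = 0.6,
                            path = NULL) {
  stopifnot(exon_bias >= 0, exon_bias <= 1, hom_prob >= 0, hom_prob <= 1)
  set.seed(seed)
  ctx <- ifelse(runif(n) < exon_bias, "Exon",
                sample(c("Intron", "Promoter", "TE"), n, replace = TRUE))
  start <- as.numeric(sort(sample.int(3e7, n)))
  len <- as.numeric(sample(3:6, n, replace = TRUE)) # target-site scale
  zyg <- ifelse(runif(n) < hom_prob, "homozygous", "heterozygous")
  records <- tibble::tibble(
    chromosome = as.character(sample(1:5, n, replace = TRUE)),
    start = start, end = start + len,
    context = ctx,
    gene_id = sprintf("AT%dG%05d", sample(1:5, n, replace = TRUE),
                      sample.int(99999, n)),
    description = sprintf("synthetic locus %d", seq_len(n)),
    zygosity = zyg)
  if (!is.null(path)) write_insertion_table(records, path)
  list(records = records,
       truth = list(n_exon = sum(ctx == "Exon"), n_hom = sum(zyg == "homozygous"),
                    n_candidates = sum(ctx == "Exon" & zyg == "homozygous")))
}

#' Synthetic genotype/aridity panel with a planted causal SNP
#'
#' Emulates a natural-accession panel: `n_ecotypes` individuals in
#' `n_groups` admixture groups, `n_snps` biallelic SNPs with Hardy-Weinberg
#' dosages at minor allele frequencies drawn from `maf_range`, and an
#' aridity response `aridity = mu + beta * g_causal + u_group + e` with
#' `u_group ~ N(0, group_sd^2)` and `e ~ N(0, 1)`. `beta` is solved so that
#' the causal SNP explains `causal_ve` percent of the total variance
#' (`beta^2 Var(g) / (beta^2 Var(g) + group_sd^2 + 1)`), using the realised
#' dosage variance. Duplicate clusters (identical ecotypes) can be planted
#' for kinship/pruning tests.
#'
#' @param n_ecotypes,n_groups,n_snps Panel dimensions.
#' @param seed RNG seed.
#' @param maf_range Range of per-SNP minor allele frequencies.
#' @param causal_ve Target variance explained by the causal SNP, percent
#'   (`0 <= causal_ve < 100`); 0 plants a null SNP.
#' @param group_sd SD of the admixture-group random effect.
#' @param duplicate_clusters Number of planted duplicate clusters.
#' @param cluster_size Ecotypes per duplicate cluster (1 original +
#'   `cluster_size - 1` copies appended).
#' @param mu Aridity intercept.
#' @return A list: `panel` (a [genotype_panel()] with groups and aridity),
#'   `truth` (`beta`, `causal_snp`, `ve`, `group_sd`, `duplicate_ids` the
#'   appended copies, `cluster_members`).
#' @export
synth_genotype_aridity <- function(n_ecotypes = 596, n_groups = 9,
                                   n_snps = 11, seed = 1,
                                   maf_range = c(0.3, 0.5), causal_ve = 4.3,
                                   group_sd = 1, duplicate_clusters = 0,
                                   cluster_size = 3, mu = 10) {
  if (causal_ve < 0 || causal_ve >= 100) abort("`causal_ve` must be in [0, 100).")
  set.seed(seed)
  mafs <- runif(n_snps, maf_range[1], maf_range[2])
  dos <- vapply(mafs, function(p) rbinom(n_ecotypes, 2, p),
                integer(n_ecotypes))
  eco <- sprintf("eco%04d", seq_len(n_ecotypes))
  pos <- sort(sample.int(5000, n_snps)) + 149000
  snp <- paste0("2_", pos)
  dimnames(dos) <- list(eco, snp)
  grp <- sample(sprintf("group%d", seq_len(n_groups)), n_ecotypes,
                replace = TRUE)
  causal <- snp[1]
  g <- dos[, causal]
  vg <- var(g)
  if (causal_ve > 0 && vg == 0) {
    abort("Causal SNP is monomorphic; requested VE unattainable.")
  }
  beta <- if (causal_ve > 0) {
    sqrt((causal_ve / 100) / (1 - causal_ve / 100) * (group_sd^2 + 1) / vg)
  } else 0
  u <- rnorm(n_groups, 0, group_sd)
  names(u) <- sprintf("group%d", seq_len(n_groups))
  aridity <- mu + beta * g + u[grp] + rnorm(n_ecotypes)
  dup_ids <- character(0); members <- list()
  if (duplicate_clusters > 0) {
    stopifnot(cluster_size >= 2, duplicate_clusters <= n_ecotypes)
    for (cl in seq_len(duplicate_clusters)) {
      orig <- eco[cl]
      copies <- sprintf("%s_dup%d", orig, seq_len(cluster_size - 1))
      dos <- rbind(dos, matrix(rep(dos[orig, ], cluster_size - 1),
                               nrow = cluster_size - 1, byrow = TRUE,
                               dimnames = list(copies, snp)))
      grp <- c(grp, rep(grp[cl], cluster_size - 1))
      aridity <- c(aridity, rep(aridity[cl], cluster_size - 1))
      dup_ids <- c(dup_ids, copies)
      members[[cl]] <- c(orig, copies)
    }
    eco <- rownames(dos)
  }
  panel <- genotype_panel(
    dos,
    positions = tibble::tibble(snp_id = snp, chromosome = "2",
                               position = pos),
    groups = tibble::tibble(ecotype = eco, group = grp),
    aridity = tibble::tibble(ecotype = eco, aridity = unname(aridity)))
  list(panel = panel,
       truth = list(beta = beta, causal_snp = causal, ve = causal_ve,
                    group_sd = group_sd, mafs = setNames(mafs, snp),
                    duplicate_ids = dup_ids, cluster_members = members))
}

#' Write a genotype panel to VCF / CSV files with a ground-truth sidecar
#'
#' Emits a GT-only VCF (`snps.vcf`), `groups.csv`, `aridity.csv` and, when
#' `truth` is given, a `truth.json` sidecar, in the formats consumed by
#' [read_genotypes()].
#'
#' @param panel A [genotype_panel()].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list to serialise as JSON.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dos <- panel$dosages
  pos <- panel$positions
  if (is.null(pos)) {
    pos <- tibble::tibble(snp_id = colnames(dos), chromosome = "1",
                          position = seq_len(ncol(dos)))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines_out <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(pos$chromosome[j], pos$position[j], pos$snp_id[j], "A", "T",
            ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(lines_out, body), file.path(dir, "snps.vcf"))
  if (!is.null(panel$groups)) {
    readr::write_csv(panel$groups, file.path(dir, "groups.csv"))
  }
  if (!is.null(panel$aridity)) {
    readr::write_csv(panel$aridity, file.path(dir, "aridity.csv"))
  }
  if (!is.null(truth)) {
    truth <- truth[!vapply(truth, is.function, TRUE)]
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Synthetic qPCR plate with planted fold changes
#'
#' Generates technical-replicate Ct values for a target/reference gene pair:
#' the reference gene sits at a common baseline, and each sample's target Ct
#' is shifted by `-log2(fold)` relative to the control, plus `N(0, sigma)`
#' measurement noise per replicate. The control sample (fold 1) is always
#' included.
#'
#' @param folds Named vector of true fold changes (names = sample ids).
#' @param seed RNG seed.
#' @param sigma Ct noise SD per technical replicate.
#' @param control Control sample id.
#' @param n_replicates Technical replicates per sample x gene.
#' @param target,reference Gene names.
#' @param base_target,base_reference Baseline Ct of the two genes in the
#'   control.
#' @return A list: `plate` tibble (`sample`, `gene`, `replicate`, `ct`) and
#'   `truth` (the fold vector including the control).
#' @export
synth_qpcr_plate <- function(folds, seed, sigma = 0.2, control = "Col0",
                             n_replicates = 3, target = "ONSEN",
                             reference = "ACTIN2", base_target = 20,
                             base_reference = 24) {
  stopifnot(all(folds > 0))
  set.seed(seed)
  if (is.null(names(folds))) names(folds) <- paste0("sample", seq_along(folds))
  all_folds <- c(setNames(1, control), folds)
  plate <- tidyr::expand_grid(sample = names(all_folds),
                              gene = c(target, reference),
                              replicate = seq_len(n_replicates)) %>%
    dplyr::mutate(
      ct = ifelse(.data$gene == reference, base_reference,
                  base_target - log2(all_folds[.data$sample])) +
        rnorm(dplyr::n(), 0, sigma))
  list(plate = plate, truth = list(folds = all_folds, sigma = sigma,
                                   control = control))
}
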