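#' Construct a genotype panel
#'
#' Container for the natural-accession stage: a dosage matrix (ecotypes x
#' SNPs, alternate-allele counts 0/1/2 with `NA` for missing), SNP positions,
#' and optional per-ecotype admixture-group labels and aridity values (the
#' environmental response, e.g. a summer-mean Global Aridity Index).
#'
#' @param dosages Integer/numeric matrix, rownames = ecotype ids, colnames =
#'   SNP ids.
#' @param positions Optional tibble `snp_id`, `chromosome`, `position`.
#' @param groups Optional tibble `ecotype`, `group`.
#' @param aridity Optional tibble `ecotype`, `aridity`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, positions = NULL, groups = NULL,
                           aridity = NULL) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    abort("`dosages` needs ecotype rownames and SNP colnames.")
  }
  vals <- dosages[!is.na(dosages)]
  if (!all(vals %in% 0:2)) abort("Dosages must be 0, 1, 2 or NA.")
  if (!is.null(groups)) {
    stopifnot(all(c("ecotype", "group") %in% names(groups)))
    if (anyDuplicated(groups$ecotype)) abort("Each ecotype must have exactly one group label.")
    groups <- dplyr::semi_join(groups,
                               tibble::tibble(ecotype = rownames(dosages)),
                               by = "ecotype")
  }
  if (!is.null(aridity)) stopifnot(all(c("ecotype", "aridity") %in% names(aridity)))
  structure(list(dosages = dosages, positions = positions, groups = groups,
                 aridity = aridity), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d ecotypes x %d SNPs; groups: %s; aridity: %s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$groups)) "none" else as.character(dplyr::n_distinct(x$groups$group)),
              if (is.null(x$aridity)) "none" else "yes"))
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF into a panel
#'
#' Extracts GT fields with `vcfR`, converts them to alternate-allele dosages
#' (0/1/2, `./.` missing) and skips multiallelic sites with a warning.
#'
#' @param vcf Path to a VCF file (GT-only subsets are sufficient).
#' @param groups,aridity Optional paths to CSVs (`ecotype,group` /
#'   `ecotype,aridity`) or equivalent tibbles.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(vcf, groups = NULL, aridity = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fmt <- v@gt
  if (is.null(fmt) || !nrow(fmt) || !any(grepl("GT", fmt[, "FORMAT"]))) {
    abort("VCF has no GT genotype fields.")
  }
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warn(sprintf("Skipping %d multiallelic site(s).", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  snp_id <- unname(ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                          paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                          fix[, "ID"]))
  rownames(dos) <- snp_id
  dos <- t(dos) # ecotypes x SNPs
  positions <- tibble::tibble(snp_id = snp_id,
                              chromosome = fix[, "CHROM"],
                              position = as.numeric(fix[, "POS"]))
  if (is.character(groups)) {
    groups <- readr::read_csv(groups, col_types = readr::cols())
  }
  if (is.character(aridity)) {
    aridity <- readr::read_csv(aridity, col_types = readr::cols())
  }
  genotype_panel(dos, positions, groups, aridity)
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_integer_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles != "0")
}

#' Minor-allele-frequency filter
#'
#' Computes per-SNP minor allele frequency over non-missing alleles and
#' retains SNPs with maf strictly greater than the threshold (the natural-
#' accession analysis used maf > 0.3). SNPs with no genotyped ecotype are
#' dropped with a warning.
#'
#' @param panel A [genotype_panel()].
#' @param threshold Strict lower bound on maf.
#' @return Character vector of retained SNP ids.
#' @export
maf_filter <- function(panel, threshold = 0.3) {
  dos <- panel$dosages
  n_called <- colSums(!is.na(dos))
  if (any(n_called == 0)) {
    warn(sprintf("Dropping %d all-missing SNP(s).", sum(n_called == 0)))
  }
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  colnames(dos)[!is.na(maf) & n_called > 0 & maf > threshold]
}

#' KING-robust kinship matrix
#'
#' Pairwise within-family KING-robust kinship over shared non-missing sites:
#' `k_ij = (N_het,het - 2 * N_opposing_hom) / (N_het,i + N_het,j)`, where
#' `N_het,het` counts sites heterozygous in both, `N_opposing_hom` counts
#' opposite homozygotes, and `N_het,i` counts heterozygous sites of `i`
#' restricted to sites genotyped in `j` (the vcftools `--relatedness2`
#' estimator). Identical genotype vectors with at least one heterozygous
#' site give exactly 0.5; pairs with no heterozygous site in either member
#' are undefined (`NA`). Diagonal is set to 0.5 by convention.
#'
#' @param panel A [genotype_panel()].
#' @return A symmetric numeric matrix with ecotype dimnames.
#' @export
king_kinship <- function(panel) {
  dos <- panel$dosages
  if (nrow(dos) < 2) abort("Need >= 2 ecotypes for kinship.")
  ok <- !is.na(dos)
  H <- (dos == 1L) & ok; storage.mode(H) <- "double"
  A0 <- (dos == 0L) & ok; storage.mode(A0) <- "double"
  A2 <- (dos == 2L) & ok; storage.mode(A2) <- "double"
  OK <- ok; storage.mode(OK) <- "double"
  n_hh <- H %*% t(H)
  n_opp <- A0 %*% t(A2) + A2 %*% t(A0)
  het_i <- H %*% t(OK) # sites het in i and genotyped in j
  denom <- het_i + t(het_i)
  k <- (n_hh - 2 * n_opp) / denom
  k[denom == 0] <- NA_real_
  diag(k) <- 0.5
  dimnames(k) <- list(rownames(dos), rownames(dos))
  k
}

#' Prune related ecotypes from a kinship matrix
#'
#' Greedy pruning to enforce a kinship ceiling: while any off-diagonal
#' kinship is at or above `cutoff`, the ecotype involved in the largest
#' number of such pairs is removed (ties broken by lexicographically first
#' id). Duplicated ecotypes therefore collapse to one representative.
#'
#' @param kinship Kinship matrix from [king_kinship()] (or a
#'   [genotype_panel()], in which case the kinship is computed first).
#' @param cutoff Remove until all pairwise kinship `< cutoff` (default 0.5).
#' @return Character vector of retained ecotype ids.
#' @export
prune_related <- function(kinship, cutoff = 0.5) {
  if (inherits(kinship, "genotype_panel")) kinship <- king_kinship(kinship)
  k <- kinship
  diag(k) <- NA_real_
  keep <- rownames(k)
  repeat {
    sub <- k[keep, keep, drop = FALSE]
    high <- !is.na(sub) & sub >= cutoff
    deg <- rowSums(high)
    if (!any(deg > 0)) break
    worst <- keep[deg == max(deg)]
    drop_id <- sort(worst)[1]
    keep <- setdiff(keep, drop_id)
  }
  keep
}

#' Pairwise linkage disequilibrium (composite r-squared)
#'
#' Squared Pearson correlation between dosage vectors over pairwise-complete
#' ecotypes. SNPs with constant dosage yield `NA` entries.
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids SNPs to include (default: all).
#' @return A symmetric r-squared matrix.
#' @export
ld_r2 <- function(panel, snp_ids = NULL) {
  dos <- panel$dosages
  if (is.null(snp_ids)) snp_ids <- colnames(dos)
  if (length(snp_ids) < 2) abort("Need >= 2 SNPs for LD.")
  x <- dos[, snp_ids, drop = FALSE]
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r2 <- r^2
  constant <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]; length(v) == 0 || all(v == v[1])
  })
  r2[constant, ] <- NA_real_
  r2[, constant] <- NA_real_
  d <- diag(r2)
  d[!constant] <- 1
  diag(r2) <- d
  r2
}

#' Heatmap of an LD matrix
#'
#' @param r2 Matrix from [ld_r2()].
#' @return A ggplot tile plot.
#' @export
plot_ld_heatmap <- function(r2) {
  df <- tibble::as_tibble(as.table(r2), .name_repair = ~c("snp1", "snp2", "r2"))
  ggplot2::ggplot(df, ggplot2::aes(.data$snp1, .data$snp2, fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
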