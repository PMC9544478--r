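tip_contexts <- c("Exon", "Intron", "Promoter", "TE")
tip_zygosities <- c("homozygous", "heterozygous")

#' Read a TIP (transposon insertion polymorphism) table
#'
#' Parses an insertion catalogue in the printed table style: tab-separated
#' with columns `chr`, `coordinates`, `context`, `gene_id`, `description`,
#' `zygosity`. Coordinate spans use the abbreviated form `A-B` where `B`
#' shares `A`'s leading digits (`149387-91` means 149387..149391); both
#' hyphen and en-dash separators are accepted. Zygosity is printed as
#' `(-/-)` (homozygous insertion) or `(+/-)` (heterozygous).
#'
#' The catalogue of the 10 heat-induced ONSEN insertions of hcLine31 ships
#' with the package: `system.file("extdata", "hcline31_insertions.tsv",
#' package = "onsenfate")`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chromosome`, `start`, `end` (1-based
#'   inclusive), `context`, `gene_id`, `description`, `zygosity`.
#' @examples
#' tips <- read_insertion_table(
#'   system.file("extdata", "hcline31_insertions.tsv", package = "onsenfate"))
#' nrow(tips) # 10
#' @export
read_insertion_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  needed <- c("chr", "coordinates", "context", "gene_id", "description",
              "zygosity")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("Missing column(s): %s.",
                  paste(setdiff(needed, names(raw)), collapse = ", ")))
  }
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    span <- parse_coordinate_span(raw$coordinates[i], line = i)
    ctx <- raw$context[i]
    if (!ctx %in% tip_contexts) {
      abort(sprintf("Row %d: unknown context '%s'.", i, ctx))
    }
    zyg <- parse_zygosity(raw$zygosity[i], line = i)
    rows[[i]] <- tibble::tibble(
      chromosome = raw$chr[i], start = span[1], end = span[2],
      context = ctx, gene_id = raw$gene_id[i],
      description = raw$description[i], zygosity = zyg)
  }
  dplyr::bind_rows(rows)
}

# "149387-91" (hyphen or en-dash) -> c(149387, 149391): the printed end keeps
# only the digits that differ, so the full end is the start with its trailing
# nchar(suffix) digits replaced.
parse_coordinate_span <- function(x, line = NA) {
  parts <- strsplit(gsub("–", "-", x), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(grepl("^[0-9]+$", parts))) {
    abort(sprintf("Row %s: malformed coordinate span '%s'.", line, x))
  }
  start_str <- parts[1]; suffix <- parts[2]
  if (nchar(suffix) > nchar(start_str)) {
    abort(sprintf("Row %s: span end '%s' longer than start.", line, x))
  }
  end_str <- paste0(substr(start_str, 1, nchar(start_str) - nchar(suffix)),
                    suffix)
  span <- as.numeric(c(start_str, end_str))
  if (span[1] > span[2]) {
    abort(sprintf("Row %s: span '%s' has start > end.", line, x))
  }
  if (span[2] - span[1] > 10) {
    abort(sprintf("Row %s: span '%s' wider than the target-site scale (10 bp).",
                  line, x))
  }
  span
}

parse_zygosity <- function(x, line = NA) {
  x <- gsub("−", "-", x) # minus sign -> hyphen
  switch(x,
    "(-/-)" = "homozygous",
    "(+/-)" = "heterozygous",
    homozygous = "homozygous",
    heterozygous = "heterozygous",
    abort(sprintf("Row %s: unknown zygosity '%s'.", line, x)))
}

#' Write a TIP table in the printed abbreviated style
#'
#' Inverse of [read_insertion_table()]: coordinate spans are re-abbreviated
#' (`A-B` with `B` reduced to the digits after the longest common prefix) and
#' zygosity rendered as `(-/-)`/`(+/-)`, so a read/write round trip
#' reproduces the file cell for cell.
#'
#' @param records Tibble as returned by [read_insertion_table()].
#' @param path Output TSV path.
#' @export
write_insertion_table <- function(records, path) {
  out <- tibble::tibble(
    chr = records$chromosome,
    coordinates = purrr::map2_chr(records$start, records$end,
                                  format_coordinate_span),
    context = records$context,
    gene_id = records$gene_id,
    description = records$description,
    zygosity = ifelse(records$zygosity == "homozygous", "(-/-)", "(+/-)"))
  readr::write_tsv(out, path)
  invisible(path)
}

# Printed convention: the end keeps at least its last two digits, more when
# the span alters higher digits.
format_coordinate_span <- function(start, end) {
  s <- format(start, scientific = FALSE, trim = TRUE)
  e <- format(end, scientific = FALSE, trim = TRUE)
  if (nchar(s) != nchar(e)) return(paste0(s, "-", e))
  cp <- 0
  for (i in seq_len(nchar(s))) {
    if (substr(s, i, i) == substr(e, i, i)) cp <- i else break
  }
  keep <- max(2, nchar(e) - cp)
  paste0(s, "-", substr(e, nchar(e) - keep + 1, nchar(e)))
}

#' Filter insertion records down to candidate causal insertions
#'
#' The candidate reasoning for a uniformly tolerant line: the causal mutation
#' must be homozygous (all replicates tolerant) and disruptive (located in an
#' exon). The default filter is therefore `context = "Exon"` and
#' `zygosity = "homozygous"`; either criterion can be relaxed with `NULL`.
#'
#' @param records Insertion tibble (see [read_insertion_table()]).
#' @param contexts Character vector of contexts to keep, or `NULL` for all.
#' @param zygosity Zygosity to keep (`"homozygous"`/`"heterozygous"`), or
#'   `NULL` for all.
#' @return The matching rows, in input order.
#' @examples
#' tips <- read_insertion_table(
#'   system.file("extdata", "hcline31_insertions.tsv", package = "onsenfate"))
#' filter_candidates(tips)$gene_id # AT1G58602, AT2G01290, AT5G03435
#' @export
filter_candidates <- function(records, contexts = "Exon",
                              zygosity = "homozygous") {
  out <- records
  if (!is.null(contexts)) {
    stopifnot(all(contexts %in% tip_contexts))
    out <- dplyr::filter(out, .data$context %in% contexts)
  }
  if (!is.null(zygosity)) {
    zygosity <- match.arg(zygosity, tip_zygosities)
    out <- dplyr::filter(out, .data$zygosity == !!zygosity)
  }
  out
}

#' Convert insertion records to BED intervals
#'
#' @param records Insertion tibble.
#' @return A tibble in BED convention (0-based half-open): `chrom`,
#'   `chromStart`, `chromEnd`, `name`.
#' @export
tips_as_bed <- function(records) {
  tibble::tibble(chrom = records$chromosome,
                 chromStart = as.integer(records$start - 1),
                 chromEnd = as.integer(records$end),
                 name = records$gene_id)
}

#' Call insertion zygosity from a PCR band pattern
#'
#' Genotyping uses two PCRs: a flanking-primer product that only amplifies
#' the empty (wild-type) site — the elongation time is too short to cross a
#' ~5 kb insertion — and an insertion-specific product. The four band
#' patterns map to calls: wild-type band only = `wt_hom`, both bands =
#' `heterozygous`, insertion band only = `insertion_hom`, neither = `failed`.
#'
#' @param wt_band_present,insertion_band_present Logical (vectorised).
#' @return Character calls.
#' @examples
#' call_zygosity_from_bands(TRUE, TRUE) # heterozygous
#' @export
call_zygosity_from_bands <- function(wt_band_present, insertion_band_present) {
  dplyr::case_when(
    wt_band_present & !insertion_band_present ~ "wt_hom",
    wt_band_present & insertion_band_present ~ "heterozygous",
    !wt_band_present & insertion_band_present ~ "insertion_hom",
    TRUE ~ "failed")
}

#' Expected F2 survival under a recessive loss-of-function model
#'
#' For a single locus where drought survival requires the absence of any
#' functional allele, enumerates the F2 of a cross (F1 selfed) and returns
#' the probability that an F2 individual carries no functional allele.
#' Crosses: `hc31_x_wt` (insertion allele x functional allele),
#' `hc31_x_rpi2` (two independent loss-of-function alleles at the same
#' locus), `wt_x_wt`.
#'
#' @param cross One of `"hc31_x_wt"`, `"hc31_x_rpi2"`, `"wt_x_wt"`.
#' @return Expected surviving fraction.
#' @examples
#' expected_f2_survival("hc31_x_wt")   # 0.25
#' expected_f2_survival("hc31_x_rpi2") # 1
#' @export
expected_f2_survival <- function(cross) {
  cross <- match.arg(cross, c("hc31_x_wt", "hc31_x_rpi2", "wt_x_wt"))
  # parental genotypes as allele pairs; "+" is the only functional allele
  # ("o" = ONSEN insertion, "t" = T-DNA insertion)
  parents <- switch(cross,
    hc31_x_wt = list(c("o", "o"), c("+", "+")),
    hc31_x_rpi2 = list(c("o", "o"), c("t", "t")),
    wt_x_wt = list(c("+", "+"), c("+", "+")))
  f1 <- c(parents[[1]][1], parents[[2]][1]) # homozygous parents: one allele each
  # F2 from selfing the F1: each allele drawn uniformly from the F1 pair
  combos <- expand.grid(a1 = f1, a2 = f1, stringsAsFactors = FALSE)
  mean(combos$a1 != "+" & combos$a2 != "+")
}
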