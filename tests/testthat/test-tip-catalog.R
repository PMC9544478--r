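test_that("the hcLine31 catalogue parses with expanded coordinate spans", {
  tips <- read_insertion_table(hcline31_path())
  expect_equal(nrow(tips), 10)
  rpi2 <- tips[tips$gene_id == "AT2G01290", ]
  expect_equal(c(rpi2$start, rpi2$end), c(149387, 149391))
  lrr <- tips[tips$gene_id == "AT1G58602", ]
  expect_equal(c(lrr$start, lrr$end), c(21761950, 21761955))
  expect_true(all(tips$start <= tips$end))
  expect_true(all(tips$end - tips$start <= 10))
  expect_true(all(tips$context %in% c("Exon", "Intron", "Promoter", "TE")))
})

test_that("malformed rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr\tcoordinates\tcontext\tgene_id\tdescription\tzygosity",
               "1\t100-xyz\tExon\tAT1G00001\tx\t(-/-)"), path)
  expect_error(read_insertion_table(path), "Row 1.*malformed")
  writeLines(c("chr\tcoordinates\tcontext\tgene_id\tdescription\tzygosity",
               "1\t100-104\tCDS\tAT1G00001\tx\t(-/-)"), path)
  expect_error(read_insertion_table(path), "unknown context")
  writeLines(c("chr\tcoordinates\tcontext\tgene_id\tdescription\tzygosity",
               "1\t100-104\tExon\tAT1G00001\tx\t(x/x)"), path)
  expect_error(read_insertion_table(path), "unknown zygosity")
  writeLines(c("chr\tcoordinates\tcontext\tgene_id\tdescription\tzygosity",
               "1\t105-01\tExon\tAT1G00001\tx\t(-/-)"), path)
  expect_error(read_insertion_table(path), "start > end")
  writeLines(c("chr\tcoordinates\tcontext\tgene_id\tdescription\tzygosity",
               "1\t100-190\tExon\tAT1G00001\tx\t(-/-)"), path)
  expect_error(read_insertion_table(path), "target-site")
})

test_that("write/read round trip reproduces the table cell for cell", {
  tips <- read_insertion_table(hcline31_path())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_insertion_table(tips, path)
  expect_identical(readLines(path), readLines(hcline31_path()))
  expect_identical(read_insertion_table(path), tips)
})

test_that("the candidate filter isolates homozygous exonic insertions", {
  tips <- read_insertion_table(hcline31_path())
  exonic <- filter_candidates(tips, contexts = "Exon", zygosity = NULL)
  expect_equal(nrow(exonic), 6)
  cands <- filter_candidates(tips)
  expect_equal(sort(cands$gene_id), c("AT1G58602", "AT2G01290", "AT5G03435"))
  # identity filter
  expect_identical(filter_candidates(tips, contexts = NULL, zygosity = NULL),
                   tips)
  expect_identical(
    filter_candidates(tips, contexts = c("Exon", "Intron", "Promoter", "TE"),
                      zygosity = NULL), tips)
})

test_that("BED export converts to 0-based half-open intervals", {
  tips <- read_insertion_table(hcline31_path())
  bed <- tips_as_bed(tips)
  expect_equal(bed$chromStart, as.integer(tips$start - 1))
  expect_equal(bed$chromEnd - bed$chromStart, as.integer(tips$end - tips$start + 1))
})

test_that("band-pattern zygosity calls cover all four patterns", {
  expect_equal(call_zygosity_from_bands(TRUE, FALSE), "wt_hom")
  expect_equal(call_zygosity_from_bands(TRUE, TRUE), "heterozygous")
  expect_equal(call_zygosity_from_bands(FALSE, TRUE), "insertion_hom")
  expect_equal(call_zygosity_from_bands(FALSE, FALSE), "failed")
  # vectorised over a gel's worth of lanes
  expect_equal(call_zygosity_from_bands(c(TRUE, FALSE), c(TRUE, TRUE)),
               c("heterozygous", "insertion_hom"))
})

test_that("F2 survival expectations follow the recessive single-locus model", {
  expect_equal(expected_f2_survival("hc31_x_wt"), 0.25)
  expect_equal(expected_f2_survival("hc31_x_rpi2"), 1)
  expect_equal(expected_f2_survival("wt_x_wt"), 0)
  expect_error(expected_f2_survival("hc31_x_hc31"))
})

test_that("synthetic catalogues round-trip and honour their knobs", {
  st <- synth_tip_table(20, seed = 4, exon_bias = 1, hom_prob = 0.5)
  expect_true(all(st$records$context == "Exon"))
  st2 <- synth_tip_table(15, seed = 6, exon_bias = 0.6, hom_prob = 0.6)
  expect_equal(nrow(filter_candidates(st2$records)), st2$truth$n_candidates)
  path <- withr::local_tempfile(fileext = ".tsv")
  synth_tip_table(12, seed = 8, path = path)
  again <- read_insertion_table(path)
  expect_equal(nrow(again), 12)
  expect_identical(again, synth_tip_table(12, seed = 8)$records)
})
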