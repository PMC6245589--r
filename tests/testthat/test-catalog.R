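test_that("catalog loading discards interactions, bad positions and weak associations", {
  toy <- write_toy_catalog()
  expect_message(cat_tbl <- load_catalog(toy$path, build = "GRCh38"),
                 "unparseable position")
  raw <- toy$records
  # brute-force reference count: drop interactions, unparseable positions,
  # p >= 1e-6, then unique (chrom, pos, trait)
  keep <- !grepl(" x |;", raw$SNPS) &
    !is.na(suppressWarnings(as.integer(raw$CHR_POS))) &
    as.numeric(raw$`P-VALUE`) < 1e-6
  ref <- raw[keep, ]
  ref_n <- nrow(unique(ref[, c("CHR_ID", "CHR_POS", "DISEASE/TRAIT")]))
  expect_equal(nrow(cat_tbl), ref_n)
  expect_false(any(grepl(" x ", cat_tbl$rsid)))
  expect_true(all(cat_tbl$p_value < 1e-6))
  # dedupe is idempotent
  again <- dplyr::distinct(tibble::as_tibble(cat_tbl),
                           chrom, pos, trait, .keep_all = TRUE)
  expect_equal(nrow(again), nrow(cat_tbl))
})

test_that("trait filtering is exact-match and the vocabularies nest", {
  lung <- trait_vocabulary("LUNG")
  cancer <- trait_vocabulary("CANCER")
  expect_true(all(lung %in% cancer))          # LUNG subset of CANCER
  expect_true("Lung cancer" %in% lung)
  expect_true("Breast cancer" %in% cancer)
  expect_false("Breast cancer" %in% lung)
  expect_null(trait_vocabulary("ALL"))

  toy <- write_toy_catalog()
  cat_tbl <- suppressMessages(load_catalog(toy$path, build = "GRCh38"))
  f_lung <- filter_traits(cat_tbl, lung)
  expect_true(all(f_lung$trait %in% c("Lung cancer", "Pulmonary function")))
  empty <- filter_traits(cat_tbl[0, ], lung)
  expect_equal(nrow(empty), 0)
  expect_error(filter_traits(cat_tbl, character(0)), "non-empty")
})

test_that("intersection hits match a nested-loop brute-force join and nest by vocabulary", {
  toy <- write_toy_catalog()
  cat_all <- suppressMessages(load_catalog(toy$path, build = "GRCh38"))
  set.seed(101)
  selected <- tibble::tibble(
    snp_id = sprintf("sel%02d", 1:12),
    chrom = c(cat_all$chrom[1:5], sample(1:5, 7, replace = TRUE)),
    pos = c(cat_all$pos[1:5], sample(3e5:4e5, 7))  # 5 shared, 7 disjoint
  )
  hits <- intersect_snps(selected, cat_all, mode = "position",
                         build = "GRCh38")
  brute <- 0L
  for (i in seq_len(nrow(selected))) {
    for (j in seq_len(nrow(cat_all))) {
      if (selected$chrom[i] == cat_all$chrom[j] &&
          selected$pos[i] == cat_all$pos[j]) {
        brute <- brute + 1L
      }
    }
  }
  expect_equal(nrow(hits), brute)
  expect_gte(nrow(hits), 5)

  h_lung <- intersect_snps(selected,
                           filter_traits(cat_all, trait_vocabulary("LUNG")),
                           mode = "position", build = "GRCh38")
  h_cancer <- intersect_snps(selected,
                             filter_traits(cat_all, trait_vocabulary("CANCER")),
                             mode = "position", build = "GRCh38")
  expect_lte(nrow(h_lung), nrow(h_cancer))
  expect_lte(nrow(h_cancer), nrow(hits))
  key <- function(h) paste(h$chrom, h$pos, h$trait)
  expect_true(all(key(h_lung) %in% key(h_cancer)))
  expect_true(all(key(h_cancer) %in% key(hits)))

  # disjoint sets: no hits; rsid mode joins on identifiers
  none <- intersect_snps(tibble::tibble(snp_id = "selX", chrom = 9L,
                                        pos = 1L),
                         cat_all, mode = "position", build = "GRCh38")
  expect_equal(nrow(none), 0)
  one <- intersect_snps(tibble::tibble(snp_id = cat_all$rsid[3]),
                        cat_all, mode = "rsid")
  expect_gte(nrow(one), 1)
})

test_that("genome builds must match for positional intersection", {
  toy <- write_toy_catalog()
  cat_all <- suppressMessages(load_catalog(toy$path, build = "GRCh37"))
  sel <- tibble::tibble(snp_id = "a", chrom = 1L, pos = 100L)
  expect_error(intersect_snps(sel, cat_all, "position", build = "GRCh38"),
               "build mismatch")
  expect_error(intersect_snps(sel, cat_all, "position"), "declare")
  expect_error(load_catalog(toy$path), "build")
})
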