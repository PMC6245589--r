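#' Load a GWAS Catalog association TSV
#'
#' Reads a v1.0-style association file (columns `CHR_ID`, `CHR_POS`,
#' `SNPS`, `DISEASE/TRAIT`, `P-VALUE`), discards multi-SNP interaction
#' entries (`"rsA x rsB"` or semicolon-separated lists), skips rows whose
#' chromosomal position does not parse (logged as a message), keeps only
#' associations with p-value strictly below `p_threshold`, and deduplicates
#' to unique (chromosome, position, trait) triples. Trait strings are
#' whitespace-normalized.
#'
#' @param path Path to the association TSV.
#' @param build Declared genome build of the catalog positions (e.g.
#'   `"GRCh38"`); required so intersections never silently mix builds.
#' @param p_threshold Inclusion threshold on the association p-value
#'   (default 1e-6).
#' @return A `catalog_table`: tibble with `chrom`, `pos`, `rsid`, `trait`,
#'   `p_value`; the build and release provenance are attributes.
#' @export
load_catalog <- function(path, build, p_threshold = 1e-6) {
  if (missing(build)) abort("the catalog's genome build must be declared")
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("CHR_ID", "CHR_POS", "SNPS", "DISEASE/TRAIT", "P-VALUE")
  if (!all(need %in% names(raw))) {
    abort(sprintf("catalog file lacks standard columns: %s",
                  paste(setdiff(need, names(raw)), collapse = ", ")))
  }
  n0 <- nrow(raw)
  interaction <- grepl(" x ", raw$SNPS, fixed = TRUE) |
    grepl(";", raw$SNPS, fixed = TRUE) | grepl(";", raw$CHR_ID, fixed = TRUE)
  raw <- raw[!interaction, , drop = FALSE]
  pos <- suppressWarnings(as.integer(raw$CHR_POS))
  chrom <- suppressWarnings(as.integer(raw$CHR_ID))
  parseable <- !is.na(pos) & !is.na(chrom)
  if (any(!parseable)) {
    message(sprintf("skipped %d row(s) with unparseable position", sum(!parseable)))
  }
  tbl <- tibble::tibble(
    chrom = chrom[parseable], pos = pos[parseable],
    rsid = raw$SNPS[parseable],
    trait = squish(raw$`DISEASE/TRAIT`[parseable]),
    p_value = suppressWarnings(as.numeric(raw$`P-VALUE`[parseable]))
  )
  tbl <- tbl[!is.na(tbl$p_value) & tbl$p_value < p_threshold, , drop = FALSE]
  tbl <- dplyr::distinct(tbl, .data$chrom, .data$pos, .data$trait,
                         .keep_all = TRUE)
  structure(tbl, class = c("catalog_table", class(tbl)),
            build = build, n_raw = n0)
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

#' Trait vocabularies for catalog filtering
#'
#' Returns the exact trait strings of the shipped vocabularies:
#' `"LUNG"` (lung-cancer related traits, 13 entries) and `"CANCER"`
#' (the extended cancer-related list, a superset of `"LUNG"`); `"ALL"`
#' means no trait filter and returns `NULL`.
#'
#' @param name `"ALL"`, `"LUNG"` or `"CANCER"`.
#' @return Character vector of trait strings, or `NULL` for `"ALL"`.
#' @export
trait_vocabulary <- function(name = c("ALL", "LUNG", "CANCER")) {
  name <- match.arg(name)
  if (name == "ALL") return(NULL)
  path <- system.file("extdata",
                      paste0("traits_", tolower(name), ".txt"),
                      package = "snpstab")
  readLines(path, encoding = "UTF-8")
}

#' Filter catalog records by a trait vocabulary
#'
#' Keeps records whose trait string exactly matches a vocabulary entry
#' (case-sensitive, after whitespace normalization on both sides). A
#' `NULL` vocabulary (the `"ALL"` list) keeps everything.
#'
#' @param catalog A `catalog_table`.
#' @param vocabulary Character vector of trait strings, e.g. from
#'   [trait_vocabulary()], or `NULL`.
#' @return The filtered `catalog_table`.
#' @export
filter_traits <- function(catalog, vocabulary) {
  if (is.null(vocabulary)) return(catalog)
  if (length(vocabulary) == 0) abort("vocabulary must be non-empty")
  keep <- catalog$trait %in% squish(vocabulary)
  out <- catalog[keep, , drop = FALSE]
  attr(out, "build") <- attr(catalog, "build")
  out
}

#' Intersect framework-selected SNPs with catalog records
#'
#' Joins the selected SNPs against the catalog either on (chromosome,
#' position) — both sides must declare the same genome build — or on rsid.
#'
#' @param selected Tibble of selected SNPs with `chrom` + `pos` (position
#'   mode) or `snp_id` holding rsids (rsid mode); e.g. the SNP rows of
#'   [rank_features()].
#' @param catalog A `catalog_table` (possibly trait-filtered).
#' @param mode `"position"` or `"rsid"`.
#' @param build Declared genome build of the selected SNPs' positions
#'   (required in position mode).
#' @return Tibble of hits: one row per (selected SNP, catalog record)
#'   match.
#' @export
intersect_snps <- function(selected, catalog, mode = c("position", "rsid"),
                           build = NULL) {
  mode <- match.arg(mode)
  selected <- tibble::as_tibble(selected)
  if (mode == "position") {
    if (is.null(build)) abort("declare the genome build of the selected SNPs")
    if (!identical(build, attr(catalog, "build"))) {
      abort(sprintf("genome build mismatch: selected %s vs catalog %s",
                    build, attr(catalog, "build")))
    }
    hits <- dplyr::inner_join(
      selected[, intersect(c("snp_id", "chrom", "pos"), names(selected))],
      tibble::as_tibble(catalog),
      by = c("chrom", "pos")
    )
  } else {
    if (!"snp_id" %in% names(selected)) abort("rsid mode needs a snp_id column")
    hits <- dplyr::inner_join(
      selected[, "snp_id", drop = FALSE],
      tibble::as_tibble(catalog),
      by = c(snp_id = "rsid"), keep = TRUE
    )
  }
  hits
}

#' Per-experiment catalog intersection counts
#'
#' For every successful experiment in a grid, counts its selected SNPs'
#' hits against the full catalog and the LUNG/CANCER trait-filtered
#' catalogs, in the layout of a per-pipeline intersection table.
#'
#' @param grid An `experiment_grid`.
#' @param catalog A `catalog_table`.
#' @param mode,build Passed to [intersect_snps()].
#' @return Tibble with one row per experiment: `fs`, `sampling`,
#'   `classifier`, `n_features`, `hits_all`, `hits_lung`, `hits_cancer`.
#' @export
catalog_intersection_table <- function(grid, catalog,
                                       mode = c("position", "rsid"),
                                       build = NULL) {
  mode <- match.arg(mode)
  vocab_lung <- trait_vocabulary("LUNG")
  vocab_cancer <- trait_vocabulary("CANCER")
  rows <- lapply(grid$report, function(exp) {
    if (exp$status != "ok") return(NULL)
    sel <- exp$ranked_features[exp$ranked_features$is_snp, , drop = FALSE]
    count <- function(cat) nrow(intersect_snps(sel, cat, mode, build))
    tibble::tibble(
      fs = exp$fs, sampling = exp$sampling, classifier = exp$classifier,
      n_features = nrow(sel),
      hits_all = count(catalog),
      hits_lung = count(filter_traits(catalog, vocab_lung)),
      hits_cancer = count(filter_traits(catalog, vocab_cancer))
    )
  })
  dplyr::bind_rows(rows)
}
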