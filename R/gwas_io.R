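#' Default column names for summary-statistic tables
#'
#' Maps internal field names to the header names expected in a
#' tab-separated GWAS summary-statistic file. Override entries via the
#' `column_map` argument of [read_summary_table()] to read other dialects.
#'
#' @return Named character vector: internal field -> file column name.
#' @export
default_column_map <- function() {
  c(chrom = "CHR", pos = "POS", effect_allele = "EA", other_allele = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N",
    n_cases = "N_CASES")
}

.mandatory_fields <- c("chrom", "pos", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")
.record_fields <- c("chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n", "n_cases")

#' Construct a GWAS summary dataset
#'
#' A `summary_dataset` bundles one trait's per-variant association records
#' with its metadata. Records are stored as a data frame with one row per
#' variant and columns `chrom` (character, no "chr" prefix), `pos` (1-based
#' integer), `effect_allele`, `other_allele` (uppercase), `eaf` (effect-allele
#' frequency, may be `NA`), `beta`, `se`, `pvalue`, `n`, `n_cases`
#' (the last two may be `NA`).
#'
#' Rows violating the record invariants (`se > 0`, `0 < pvalue <= 1`,
#' `pos >= 1`, alleles distinct, `eaf` in (0,1) when present, `n >= 2` when
#' present) are rejected; the rejection log is attached as
#' `attr(x, "rejections")`. Duplicate variants (same chrom, pos and allele
#' pair) keep the lowest-p row. Exact zero p-values are clamped to the
#' smallest positive double and noted in `attr(x, "notes")`.
#'
#' @param records Data frame of association records (see Details).
#' @param trait_name Trait label.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param population Population label (default `"European"`).
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name,
                            trait_type = c("binary", "continuous"),
                            population = "European") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  for (f in setdiff(.record_fields, names(records))) records[[f]] <- NA
  records <- records[.record_fields]

  records$chrom <- sub("^chr", "", as.character(records$chrom),
                       ignore.case = TRUE)
  records$pos <- suppressWarnings(as.integer(records$pos))
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (f in c("eaf", "beta", "se", "pvalue")) {
    records[[f]] <- suppressWarnings(as.numeric(records[[f]]))
  }
  for (f in c("n", "n_cases")) {
    records[[f]] <- suppressWarnings(as.integer(round(as.numeric(records[[f]]))))
  }

  notes <- data.frame(row = integer(), note = character())
  clamp <- !is.na(records$pvalue) & records$pvalue == 0
  if (any(clamp)) {
    records$pvalue[clamp] <- .Machine$double.xmin
    notes <- rbind(notes, data.frame(row = which(clamp),
                                     note = "pvalue_clamped_from_zero"))
  }

  reason <- rep(NA_character_, nrow(records))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  bad(is.na(records$pos) | records$pos < 1, "bad_position")
  bad(is.na(records$chrom) | records$chrom == "", "bad_chromosome")
  bad(is.na(records$effect_allele) | is.na(records$other_allele) |
        records$effect_allele == "" | records$other_allele == "" |
        records$effect_allele == records$other_allele, "bad_alleles")
  bad(is.na(records$beta), "missing_beta")
  bad(is.na(records$se) | records$se <= 0, "nonpositive_se")
  bad(is.na(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
      "pvalue_out_of_range")
  bad(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1),
      "eaf_out_of_range")
  bad(!is.na(records$n) & records$n < 2, "bad_sample_size")

  rejections <- data.frame(row = which(!is.na(reason)),
                           reason = reason[!is.na(reason)])
  kept <- records[is.na(reason), , drop = FALSE]

  # duplicate (chrom, pos, EA, OA): retain the lowest-p record
  key <- paste(kept$chrom, kept$pos, kept$effect_allele, kept$other_allele)
  if (anyDuplicated(key)) {
    ord <- order(kept$pvalue)
    drop_idx <- ord[duplicated(key[ord])]
    notes <- rbind(notes, data.frame(row = sort(drop_idx),
                                     note = "duplicate_variant_dropped"))
    kept <- kept[-drop_idx, , drop = FALSE]
  }
  kept <- kept[order(kept$chrom, kept$pos), , drop = FALSE]
  rownames(kept) <- NULL

  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         population = population, records = kept),
    rejections = rejections, notes = notes,
    class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset: %s (%s, %s)\n",
              x$trait_name, x$trait_type, x$population))
  cat(sprintf("  %d variant records", nrow(x$records)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej) > 0)
    cat(sprintf(", %d rows rejected on read", nrow(rej)))
  cat("\n")
  invisible(x)
}

#' Number of records in a summary dataset
#' @param x A `summary_dataset`.
#' @export
n_records <- function(x) nrow(x$records)

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated table with a header row into a [summary_dataset].
#' Column names are resolved through `column_map`, so tables in any dialect
#' can be read by remapping; unmapped optional fields (`eaf`, `n`,
#' `n_cases`) are filled with `NA`. Invalid rows are rejected, not fatal;
#' inspect `attr(ds, "rejections")`.
#'
#' @param path File path of the tab-separated table.
#' @param column_map Named character vector overriding entries of
#'   [default_column_map()] (internal field -> file column name).
#' @param trait_name,trait_type,population Trait metadata passed to
#'   [summary_dataset()].
#' @return A `summary_dataset`.
#' @export
read_summary_table <- function(path, column_map = NULL, trait_name = path,
                               trait_type = c("binary", "continuous"),
                               population = "European") {
  if (!file.exists(path)) stop("cannot read summary table: ", path)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(map[.mandatory_fields], names(raw))
  if (length(missing_cols) > 0) {
    stop("summary table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in .record_fields) {
    records[[f]] <- if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NA
  }
  ds <- summary_dataset(records, trait_name = trait_name,
                        trait_type = trait_type, population = population)
  if (nrow(ds$records) == 0) {
    stop("no valid rows in summary table: ", path)
  }
  ds
}

#' Write a summary dataset as a tab-separated table
#'
#' Writes the default-dialect table (columns CHR, POS, EA, OA, EAF, BETA,
#' SE, P, N, N_CASES). Numeric fields are written with 17 significant
#' digits so that [read_summary_table()] round-trips the dataset exactly.
#'
#' @param ds A non-empty `summary_dataset`.
#' @param path Output file path.
#' @export
write_summary_table <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (nrow(ds$records) == 0) stop("refusing to write an empty dataset")
  out <- ds$records
  for (f in c("eaf", "beta", "se", "pvalue")) {
    out[[f]] <- ifelse(is.na(out[[f]]), NA, sprintf("%.17g", out[[f]]))
  }
  names(out) <- default_column_map()[names(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# "chrom:pos" key used to match variants across datasets; positions are
# printed as plain integers regardless of storage mode
variant_id <- function(records) {
  sprintf("%s:%d", records$chrom, as.integer(records$pos))
}

# TRUE for simple SNPs (single-base A/C/G/T alleles); indels and
# multi-base alleles are retained in datasets but cannot be harmonized
is_snp <- function(records) {
  nt <- c("A", "C", "G", "T")
  records$effect_allele %in% nt & records$other_allele %in% nt
}
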