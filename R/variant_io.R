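# Variant parsing, reference validation and grouping.
#
# Variants are held in a data.table with columns:
#   chrom, pos (1-based first ref base), ref, alt, vclass, id, ref_valid,
#   src_row (input record number, for error reporting)
# vclass follows the usual conventions: SNP (1 bp -> 1 bp), INS (ref a proper
# prefix of alt), DEL (alt a proper prefix of ref), MNV (anything else,
# e.g. adjacent substitutions or complex replacements).

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
    ifelse(nchar(alt) > nchar(ref) & startsWith(alt, ref), "INS",
      ifelse(nchar(ref) > nchar(alt) & startsWith(ref, alt), "DEL", "MNV")))
}

empty_variants <- function() {
  data.table(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character(), id = character(),
             ref_valid = logical(), src_row = integer())
}

skip_row <- function(row, id, reason, detail = "") {
  data.table(src_row = as.integer(row), id = as.character(id),
             reason = reason, detail = detail)
}

#' Parse variants from VCF or CSV
#'
#' Reads a variant set from a VCF v4.x file (plain or gzipped; INFO/FORMAT
#' columns are ignored) or from the simple CSV dialect with header
#' `chrom,pos,ref,alt[,id]` and 1-based positions. `format = "auto"` decides
#' by file extension, falling back to content sniffing for the
#' `##fileformat=VCF` header line.
#'
#' Multi-allelic VCF records are split into one variant per ALT allele.
#' Records are kept in file order and never deduplicated. Symbolic or
#' structural ALT alleles (`<DEL>`, breakends) and alleles containing
#' non-ACGT characters are skipped with a warning, as are variants whose
#' reference allele is longer than `max_ref_len` (an indel longer than the
#' protospacer cannot be contained in a single guide).
#'
#' @param path input file path.
#' @param format `"auto"`, `"vcf"` or `"csv"`.
#' @param max_ref_len maximum reference-allele span accepted (default 20).
#' @return a `data.table` of variants (see details); skipped records are
#'   attached as the `"skipped"` attribute (columns `src_row`, `id`,
#'   `reason`, `detail`).
#' @export
parse_variants <- function(path, format = c("auto", "vcf", "csv"),
                           max_ref_len = 20L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  if (format == "auto") {
    lowered <- tolower(path)
    if (grepl("\\.vcf(\\.gz|\\.bgz)?$", lowered)) {
      format <- "vcf"
    } else if (grepl("\\.csv$", lowered)) {
      format <- "csv"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      format <- if (length(first) && startsWith(first, "##fileformat=VCF"))
        "vcf" else "csv"
    }
  }
  raw <- if (format == "vcf") read_vcf_records(path) else read_csv_records(path)
  finalize_variants(raw$records, raw$skipped, max_ref_len)
}

read_vcf_records <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  records <- list()
  skipped <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    rid <- fix[i, "ID"]
    ref <- toupper(fix[i, "REF"])
    alt_field <- fix[i, "ALT"]
    if (is.na(chrom) || is.na(pos) || is.na(ref) || is.na(alt_field) ||
        pos < 1L) {
      stop("malformed VCF record ", i, " in ", path, call. = FALSE)
    }
    base_id <- if (is.na(rid) || rid == ".") sprintf("var%04d", i) else rid
    alts <- toupper(strsplit(alt_field, ",", fixed = TRUE)[[1]])
    multi <- length(alts) > 1L
    for (k in seq_along(alts)) {
      alt <- alts[k]
      vid <- if (multi) paste0(base_id, "_", k) else base_id
      if (grepl("[][<>*]", alt)) {
        skipped[[length(skipped) + 1L]] <-
          skip_row(i, vid, "symbolic_alt", alt)
        next
      }
      if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
        skipped[[length(skipped) + 1L]] <-
          skip_row(i, vid, "non_acgt_allele", paste0(ref, ">", alt))
        next
      }
      records[[length(records) + 1L]] <-
        data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   id = vid, src_row = i)
    }
  }
  list(records = records, skipped = skipped)
}

read_csv_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("CSV must have header chrom,pos,ref,alt[,id]; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  records <- list()
  skipped <- list()
  for (i in seq_len(nrow(df))) {
    pos <- suppressWarnings(as.integer(df$pos[i]))
    ref <- toupper(df$ref[i])
    alt <- toupper(df$alt[i])
    if (is.na(pos) || pos < 1L || !nzchar(ref) || !nzchar(alt) ||
        !nzchar(df$chrom[i])) {
      stop("malformed CSV row ", i, " in ", path, call. = FALSE)
    }
    vid <- if ("id" %in% names(df) && nzchar(df$id[i])) df$id[i]
           else sprintf("var%04d", i)
    if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
      skipped[[length(skipped) + 1L]] <-
        skip_row(i, vid, "non_acgt_allele", paste0(ref, ">", alt))
      next
    }
    records[[length(records) + 1L]] <-
      data.table(chrom = df$chrom[i], pos = pos, ref = ref, alt = alt,
                 id = vid, src_row = i)
  }
  list(records = records, skipped = skipped)
}

finalize_variants <- function(records, skipped, max_ref_len) {
  dt <- if (length(records)) rbindlist(records) else empty_variants()
  skipped <- if (length(skipped)) rbindlist(skipped) else
    skip_row(integer(), character(), character())[0L]
  if (nrow(dt)) {
    same <- dt$ref == dt$alt
    if (any(same)) {
      skipped <- rbind(skipped, skip_row(dt$src_row[same], dt$id[same],
                                         "ref_equals_alt",
                                         paste0(dt$ref[same], ">", dt$alt[same])))
      dt <- dt[!same]
    }
  }
  if (nrow(dt)) {
    long <- nchar(dt$ref) > max_ref_len
    if (any(long)) {
      skipped <- rbind(skipped, skip_row(dt$src_row[long], dt$id[long],
                                         "ref_span_too_long",
                                         paste0(nchar(dt$ref[long]), " bp")))
      dt <- dt[!long]
    }
  }
  if (nrow(skipped)) {
    warning(nrow(skipped), " variant record(s) skipped (",
            paste(unique(skipped$reason), collapse = ", "), ")",
            call. = FALSE)
  }
  if (nrow(dt)) {
    dt[, `:=`(vclass = variant_class(ref, alt), ref_valid = NA)]
    dt[, id := make.unique(id, sep = "_dup")]
    setcolorder(dt, c("chrom", "pos", "ref", "alt", "vclass", "id",
                      "ref_valid", "src_row"))
  } else {
    dt <- empty_variants()
  }
  setattr(dt, "skipped", skipped)
  dt[]
}

#' Validate stated reference alleles against the genome
#'
#' Checks, for each variant, that the genome sequence at
#' `[pos, pos + nchar(ref))` equals the stated reference allele, and sets the
#' `ref_valid` flag accordingly. A mismatch usually means the variant
#' coordinates come from a different genome assembly version. Variants on
#' unknown chromosomes get `ref_valid = NA`. The per-variant findings
#' (including the bases actually present in the genome) are attached as the
#' `"report"` attribute.
#'
#' Downstream, mismatching variants are excluded from design when
#' `strict = TRUE` (the default in [run_config()]) or force-designed with the
#' user-stated allele when `strict = FALSE`.
#'
#' @param variants a variant `data.table` from [parse_variants()].
#' @param store a `genome_store`.
#' @return the variant table with `ref_valid` filled in; attribute
#'   `"report"` is a `data.table` (`id`, `reason`, `found`) for each variant
#'   that did not validate.
#' @export
validate_reference <- function(variants, store) {
  stopifnot(inherits(store, "genome_store"))
  out <- copy(variants)
  report <- list()
  if (nrow(out)) {
    valid <- rep(NA, nrow(out))
    for (i in seq_len(nrow(out))) {
      ch <- out$chrom[i]
      if (!ch %in% names(store$sequences)) {
        report[[length(report) + 1L]] <-
          data.table(id = out$id[i], reason = "unknown_chromosome", found = "")
        next
      }
      span_end <- out$pos[i] + nchar(out$ref[i]) - 1L
      if (span_end > store$lengths[[ch]]) {
        valid[i] <- FALSE
        report[[length(report) + 1L]] <-
          data.table(id = out$id[i], reason = "ref_mismatch",
                     found = "beyond chromosome end")
        next
      }
      found <- substr(store$sequences[[ch]], out$pos[i], span_end)
      valid[i] <- identical(found, out$ref[i])
      if (!valid[i]) {
        report[[length(report) + 1L]] <-
          data.table(id = out$id[i], reason = "ref_mismatch", found = found)
      }
    }
    out[, ref_valid := valid]
  }
  report <- if (length(report)) rbindlist(report) else
    data.table(id = character(), reason = character(), found = character())
  if (nrow(report)) {
    message(nrow(report), " variant(s) failed reference validation")
  }
  setattr(out, "report", report)
  out[]
}

#' Group variants for individual or combined targeting
#'
#' In `individual` mode every variant becomes its own singleton design
#' target. In `combined` mode variants on the same chromosome are clustered
#' by single linkage: consecutive variants whose start positions are at most
#' `window - 1` bp apart (so that both can fall inside one
#' protospacer + PAM window) join the same cluster, and each cluster is
#' designed together. Clusters containing variants with overlapping
#' reference spans are rejected with a warning — such variants cannot be
#' applied to one template simultaneously. Which variants of a combined
#' group are actually applied and lowercased in a given guide is re-checked
#' per design footprint in [enumerate_guides()].
#'
#' @param variants validated variant `data.table`.
#' @param mode `"individual"` or `"combined"`.
#' @param window clustering window in bp; defaults to 23 (20-nt protospacer
#'   + 3-nt PAM).
#' @return a list of `variant_group` objects (fields `id`, `chrom`, `mode`,
#'   `variants`); rejected clusters are attached as the `"rejected"`
#'   attribute (`ids`, `reason`).
#' @export
group_variants <- function(variants, mode = c("individual", "combined"),
                           window = 23L) {
  mode <- match.arg(mode)
  groups <- list()
  rejected <- list()
  if (nrow(variants) == 0L) {
    out <- list()
    attr(out, "rejected") <- data.table(ids = character(), reason = character())
    return(out)
  }
  if (mode == "individual") {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i]
      groups[[length(groups) + 1L]] <- new_variant_group(v$id, v, mode)
    }
  } else {
    for (ch in unique(variants$chrom)) {
      dv <- variants[chrom == ch][order(pos)]
      cl <- cumsum(c(1L, diff(dv$pos) > window - 1L))
      for (g in unique(cl)) {
        gv <- dv[cl == g]
        if (nrow(gv) > 1L) {
          span_end <- gv$pos + nchar(gv$ref) - 1L
          if (any(span_end[-nrow(gv)] >= gv$pos[-1L])) {
            rejected[[length(rejected) + 1L]] <-
              data.table(ids = paste(gv$id, collapse = ";"),
                         reason = "overlapping_ref_spans")
            next
          }
        }
        gid <- paste(gv$id, collapse = "+")
        groups[[length(groups) + 1L]] <- new_variant_group(gid, gv, mode)
      }
    }
  }
  rejected <- if (length(rejected)) rbindlist(rejected) else
    data.table(ids = character(), reason = character())
  if (nrow(rejected)) {
    warning(nrow(rejected), " variant cluster(s) rejected: overlapping ",
            "reference spans", call. = FALSE)
  }
  attr(groups, "rejected") <- rejected
  groups
}

new_variant_group <- function(id, variants, mode) {
  structure(
    list(id = id, chrom = variants$chrom[1L], mode = mode,
         variants = copy(variants)[order(pos)]),
    class = "variant_group"
  )
}

#' @export
print.variant_group <- function(x, ...) {
  cat("<variant_group> ", x$id, " (", x$mode, "): ",
      nrow(x$variants), " variant(s) on ", x$chrom, "\n", sep = "")
  invisible(x)
}

#' Write variants in the CSV dialect
#'
#' Serialises a variant table to the `chrom,pos,ref,alt,id` CSV dialect read
#' by [parse_variants()]; the round trip is lossless for valid rows.
#'
#' @param variants variant `data.table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variants_csv <- function(variants, path) {
  out <- variants[, .(chrom, pos, ref, alt, id)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
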