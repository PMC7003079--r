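# Batch orchestration: parse -> validate -> group -> template -> enumerate
# -> poly-T filter -> score -> canonical result table.

#' Build a pipeline run configuration
#'
#' Collects and validates all knobs of a design run. Defaults follow the
#' package's standard conditions: individual targeting, NGG design PAM
#' (off-target search always considers NGG and NAG), up to 3 mismatches in
#' the off-target search, a 25-bp template flank and the poly-T filter at
#' runs of 4+.
#'
#' @param genome path to the reference genome FASTA.
#' @param variants path to the variant file (VCF or CSV).
#' @param alt_genome optional path to an alternate (non-reference) genome
#'   FASTA; when given, variant guides are searched against it for
#'   specificity instead of the reference.
#' @param mode `"individual"` (one design target per variant) or
#'   `"combined"` (nearby variants targeted together).
#' @param pams design PAM set, subset of `c("NGG", "NAG")`.
#' @param max_mm off-target search mismatch radius (0..5 sensible).
#' @param flank template window flank in bp.
#' @param maxT longest permitted T run in the variant protospacer.
#' @param matrix optional path to an efficiency matrix TSV; default is the
#'   bundled matrix.
#' @param threads worker count; work is partitioned by chromosome and
#'   results are merged in canonical order, so output is identical for any
#'   value.
#' @param strict when `TRUE` (default) variants whose stated reference
#'   allele mismatches the genome are excluded (with a warnings-report
#'   line); when `FALSE` they are designed using the user-stated allele.
#' @param max_batch optional cap on the number of parsed variants
#'   (exceeding it is an error); `NULL` means unlimited.
#' @param format variant file format, `"auto"`, `"vcf"` or `"csv"`.
#' @return a `run_config` object.
#' @export
run_config <- function(genome, variants, alt_genome = NULL,
                       mode = c("individual", "combined"), pams = "NGG",
                       max_mm = 3L, flank = 25L, maxT = 3L, matrix = NULL,
                       threads = 1L, strict = TRUE, max_batch = NULL,
                       format = "auto") {
  mode <- match.arg(mode)
  stopifnot(all(pams %in% c("NGG", "NAG")), length(pams) >= 1L)
  stopifnot(threads >= 1L, max_mm >= 0L, flank >= 23L, maxT >= 1L)
  if (!file.exists(genome)) stop("genome not found: ", genome, call. = FALSE)
  if (!file.exists(variants)) stop("variants not found: ", variants, call. = FALSE)
  if (!is.null(alt_genome) && !file.exists(alt_genome)) {
    stop("alternate genome not found: ", alt_genome, call. = FALSE)
  }
  if (!is.null(matrix) && !file.exists(matrix)) {
    stop("matrix file not found: ", matrix, call. = FALSE)
  }
  structure(
    list(genome = genome, variants = variants, alt_genome = alt_genome,
         mode = mode, pams = pams, max_mm = as.integer(max_mm),
         flank = as.integer(flank), maxT = as.integer(maxT),
         matrix = matrix, threads = as.integer(threads), strict = strict,
         max_batch = max_batch, format = format),
    class = "run_config"
  )
}

empty_warnings <- function() {
  data.table(stage = character(), id = character(), reason = character(),
             detail = character())
}

#' Run the full guide design pipeline
#'
#' Executes every stage — parsing, reference validation, grouping, template
#' construction, guide enumeration, poly-T filtering and two-allele scoring
#' — and returns the canonical result table. Per-variant problems become
#' warnings-report rows, never aborts; zero designs with explanatory
#' warnings is a legal outcome. Rows are sorted by
#' (chrom, target_start, strand, variant_ids) after merging per-chromosome
#' work, so the output is byte-identical for any `threads` value.
#'
#' @param config a `run_config`.
#' @return a `varguide_result`: list with `results` (one row per design),
#'   `warnings` (`stage`, `id`, `reason`, `detail`), `stats` (stage counts)
#'   and `matrix_name`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  store <- load_genome(config$genome)
  alt_store <- if (!is.null(config$alt_genome)) load_genome(config$alt_genome)
  warnings <- empty_warnings()

  vars <- parse_variants(config$variants, config$format)
  sk <- attr(vars, "skipped")
  if (nrow(sk)) {
    warnings <- rbind(warnings,
                      sk[, .(stage = "parse", id, reason, detail)])
  }
  if (!is.null(config$max_batch) && nrow(vars) > config$max_batch) {
    stop("batch of ", nrow(vars), " variants exceeds --max-batch limit of ",
         config$max_batch, call. = FALSE)
  }

  vars <- validate_reference(vars, store)
  rep <- attr(vars, "report")
  if (nrow(rep)) {
    warnings <- rbind(warnings,
                      rep[, .(stage = "validate", id, reason, detail = found)])
  }
  usable <- vars[!is.na(ref_valid) & (ref_valid | !config$strict)]

  groups <- group_variants(usable, config$mode, window = 23L)
  rej <- attr(groups, "rejected")
  if (nrow(rej)) {
    warnings <- rbind(warnings,
                      rej[, .(stage = "group", id = ids, reason,
                              detail = "")])
  }

  matrix <- if (is.null(config$matrix)) default_efficiency_matrix()
            else read_efficiency_matrix(config$matrix)
  ref_index <- build_offtarget_index(store)
  alt_index <- if (!is.null(alt_store)) build_offtarget_index(alt_store)

  by_chrom <- split(groups, vapply(groups, function(g) g$chrom, character(1)))
  worker <- function(gs) {
    rows <- list()
    notes <- list()
    n_enum <- 0L
    n_polyt <- 0L
    for (g in gs) {
      tpl <- suppressMessages(build_template(g, store, config$flank))
      if (is.null(tpl)) {
        notes[[length(notes) + 1L]] <-
          data.table(stage = "template", id = g$id,
                     reason = "window_unusable", detail = "")
        next
      }
      des <- enumerate_guides(tpl, config$pams)
      n_enum <- n_enum + nrow(des)
      des <- suppressMessages(filter_polyt(des, config$maxT))
      n_polyt <- n_polyt + attr(des, "n_removed")
      if (nrow(des) == 0L) {
        notes[[length(notes) + 1L]] <-
          data.table(stage = "design", id = g$id,
                     reason = "no_design_found", detail = "")
        next
      }
      des[, offsets := NULL]
      rows[[length(rows) + 1L]] <-
        score_designs(des, matrix, ref_index, alt_index, config$max_mm)
    }
    list(rows = if (length(rows)) rbindlist(rows) else NULL,
         notes = if (length(notes)) rbindlist(notes) else NULL,
         n_enum = n_enum, n_polyt = n_polyt)
  }

  use_fork <- config$threads > 1L && .Platform$OS.type == "unix" &&
    length(by_chrom) > 1L
  parts <- if (use_fork) {
    parallel::mclapply(by_chrom, worker, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(by_chrom, worker)
  }

  rows <- rbindlist(Filter(Negate(is.null), lapply(parts, `[[`, "rows")))
  notes <- rbindlist(Filter(Negate(is.null), lapply(parts, `[[`, "notes")))
  if (nrow(notes)) warnings <- rbind(warnings, notes)
  if (nrow(rows)) {
    setorder(rows, chrom, target_start, strand, variant_ids)
  } else {
    rows <- score_designs(empty_designs(), matrix, ref_index, alt_index,
                          config$max_mm)
  }

  # conservation: every usable variant appears in >= 1 row or >= 1 warning
  if (nrow(usable)) {
    seen <- unique(unlist(strsplit(rows$variant_ids, ";", fixed = TRUE)))
    warned <- unique(unlist(strsplit(warnings$id, "[;+]")))
    missing <- setdiff(usable$id, c(seen, warned))
    if (length(missing)) {
      warnings <- rbind(warnings,
                        data.table(stage = "design", id = missing,
                                   reason = "no_design_found", detail = ""))
    }
  }
  setorder(warnings, stage, id)

  stats <- list(
    parsed = nrow(vars) + nrow(sk),
    accepted = nrow(vars),
    validated = sum(vars$ref_valid, na.rm = TRUE),
    designed_from = nrow(usable),
    groups = length(groups),
    enumerated = sum(vapply(parts, `[[`, integer(1), "n_enum")),
    polyt_removed = sum(vapply(parts, `[[`, integer(1), "n_polyt")),
    scored = nrow(rows)
  )
  structure(
    list(results = rows, warnings = warnings, stats = stats,
         matrix_name = matrix$name, config = config),
    class = "varguide_result"
  )
}

#' @export
print.varguide_result <- function(x, ...) {
  cat("<varguide_result> ", nrow(x$results), " design(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  cat("  stage counts: ",
      paste(names(x$stats), unlist(x$stats), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

result_columns <- c(
  "variant_ids", "chrom", "target_start", "target_end", "strand",
  "wt_sequence", "var_sequence", "pam_class", "variant_dists",
  "eff_wt", "eff_var", "spec_wt", "spec_var",
  "ontarget_wt_mm", "ontarget_var_mm", "hits_wt_by_mm", "hits_var_by_mm",
  "polyt_wt", "polyt_var", "group_id", "note"
)

#' Write the result table
#'
#' Writes designs as CSV (RFC-4180) or TSV with leading `#` comment lines
#' stamping the package version and the efficiency-matrix version. Scores
#' are written with two decimals, so files are stable across runs.
#'
#' @param x a `varguide_result` or a plain design `data.table`.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  matrix_name <- if (inherits(x, "varguide_result")) x$matrix_name else "unknown"
  rows <- if (inherits(x, "varguide_result")) x$results else x
  out <- as.data.frame(copy(rows)[, intersect(result_columns, names(rows)),
                                  with = FALSE])
  for (col in c("eff_wt", "eff_var", "spec_wt", "spec_var")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.2f", out[[col]])
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# varguide ", as.character(utils::packageVersion("varguide"))),
    paste0("# matrix: ", matrix_name)
  ), con)
  utils::write.table(out, con, sep = sep, quote = (format == "csv"),
                     qmethod = "double", row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path (`.csv` or `.tsv`; detected by extension).
#' @return a `data.table`.
#' @export
read_results <- function(path) {
  sep <- if (grepl("\\.tsv$", tolower(path))) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(variant_dists = "character"))
  as.data.table(df)
}

#' Write the warnings report
#'
#' @param x a `varguide_result`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_warnings <- function(x, path) {
  stopifnot(inherits(x, "varguide_result"))
  utils::write.table(x$warnings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
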