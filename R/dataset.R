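# Construction of labeled training sets from bicistronic-assay activity
# tables, and a synthetic fixture generator with the same schema.
#
# An assay table is a data.frame with columns:
#   id, sequence (character residues), category, ires_activity,
#   splicing_score, promoter_activity, and (after assign_labels) label.

#' Default native-sequence categories
#'
#' The screen categories retained when reducing the published assay table
#' to native (non-synthetic) sequences.
#' @export
NATIVE_CATEGORIES <- c(
  "CDS_screen", "Genome_Wide_Sceen_Elements", "High_Priority_Genes_Blocks",
  "High_Priority_Viruses_Blocks", "Human_5UTR_Screen", "IRESite_blocks",
  "Viral_5UTR_Screen", "rRNA_Matching_5UTRs"
)

#' Dataset filter configuration
#'
#' All three thresholds are strict inequalities: records are kept when
#' `splicing_score > splicing_min` and `promoter_activity < promoter_max`,
#' and labeled IRES when `ires_activity > activity_threshold`. Boundary
#' records are therefore excluded / nonIRES.
#'
#' @param allowed_categories Non-empty character vector of retained screen
#'   categories.
#' @param splicing_min Exclusive lower bound on the splicing score
#'   (default -2.5).
#' @param promoter_max Exclusive upper bound on promoter activity
#'   (default 0.2).
#' @param activity_threshold Exclusive IRES-activity cutoff (default 600).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(allowed_categories = NATIVE_CATEGORIES,
                          splicing_min = -2.5, promoter_max = 0.2,
                          activity_threshold = 600) {
  if (length(allowed_categories) == 0L) {
    stop("filter_config: allowed_categories must be non-empty", call. = FALSE)
  }
  stopifnot(is.finite(splicing_min), is.finite(promoter_max),
            is.finite(activity_threshold))
  structure(list(allowed_categories = as.character(allowed_categories),
                 splicing_min = splicing_min, promoter_max = promoter_max,
                 activity_threshold = activity_threshold),
            class = "filter_config")
}

check_assay_table <- function(records, need = character(0)) {
  stopifnot(is.data.frame(records))
  base <- c("id", "sequence", "category", "ires_activity", "splicing_score",
            "promoter_activity")
  missing <- setdiff(base, names(records))
  if (length(missing)) {
    stop(sprintf("assay table lacks columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in need) {
    bad <- records$id[!is.finite(records[[col]])]
    if (length(bad)) {
      stop(sprintf("validation error: missing/non-finite %s for ids: %s",
                   col, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Retain native (non-synthetic) assay records
#'
#' Keeps exactly the records whose `category` is in the allowed set,
#' preserving order. Sequences and scores are never modified.
#'
#' @param records Assay table data.frame.
#' @param cfg A [filter_config()].
#' @return Filtered data.frame (possibly empty).
#' @export
filter_native <- function(records, cfg = filter_config()) {
  check_assay_table(records)
  stopifnot(inherits(cfg, "filter_config"))
  records[records$category %in% cfg$allowed_categories, , drop = FALSE]
}

#' Apply splicing/promoter quality filters
#'
#' Retains records with `splicing_score > splicing_min` (default -2.5) and
#' `promoter_activity < promoter_max` (default 0.2); both bounds strict.
#'
#' @inheritParams filter_native
#' @return Filtered data.frame.
#' @export
apply_quality_filters <- function(records, cfg = filter_config()) {
  check_assay_table(records, need = c("splicing_score", "promoter_activity"))
  stopifnot(inherits(cfg, "filter_config"))
  keep <- records$splicing_score > cfg$splicing_min &
    records$promoter_activity < cfg$promoter_max
  records[keep, , drop = FALSE]
}

#' Assign IRES / nonIRES labels by activity threshold
#'
#' Labels a record IRES iff `ires_activity > activity_threshold` (strict;
#' default 600), else nonIRES. Class counts and their ratio are attached
#' as the `"class_counts"` attribute and printed via `message()`.
#'
#' @inheritParams filter_native
#' @param quiet Suppress the class-count message.
#' @return The table with a `label` factor column (levels nonIRES, IRES).
#' @export
assign_labels <- function(records, cfg = filter_config(), quiet = FALSE) {
  check_assay_table(records, need = "ires_activity")
  stopifnot(inherits(cfg, "filter_config"))
  lab <- ifelse(records$ires_activity > cfg$activity_threshold, "IRES", "nonIRES")
  records$label <- factor(lab, levels = c("nonIRES", "IRES"))
  counts <- c(IRES = sum(lab == "IRES"), nonIRES = sum(lab == "nonIRES"))
  attr(records, "class_counts") <- counts
  if (!quiet) {
    message(sprintf("assign_labels: %d IRES, %d nonIRES (ratio 1:%.1f)",
                    counts["IRES"], counts["nonIRES"],
                    if (counts["IRES"] > 0) counts["nonIRES"] / counts["IRES"] else NA))
  }
  records
}

#' Read an assay table with schema mapping
#'
#' Reads a TSV/CSV activity table and renames columns to the package schema
#' via a plain `key = value` mapping file (`package_column = file_column`),
#' since deposited layouts vary.
#'
#' @param path Table path (TSV or CSV by extension).
#' @param schema Optional path to a key-value mapping file.
#' @return Assay table data.frame.
#' @export
read_assay_table <- function(path, schema = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!is.null(schema)) {
    map <- read_kv_config(schema)
    for (pkg_col in names(map)) {
      src <- map[[pkg_col]]
      if (!src %in% names(df)) {
        stop(sprintf("schema error: column '%s' (for %s) not in table",
                     src, pkg_col), call. = FALSE)
      }
      names(df)[names(df) == src] <- pkg_col
    }
  }
  check_assay_table(df)
  df
}

# plain "key = value" config reader, '#' comments allowed
read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop(sprintf("config parse error at: %s", lines[bad][1]), call. = FALSE)
  }
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Synthetic signal configuration for the fixture generator
#'
#' Describes the planted discriminative signal: background base frequencies
#' for the negative class and a U/pyrimidine-enriched composition for the
#' positive class, optionally with a planted hairpin (an inserted stem-loop
#' whose two arms are reverse complements, so folding engines pair them).
#'
#' @param neg_freqs,pos_freqs Named numeric vectors over A/C/G/U summing
#'   to 1. Defaults: uniform background; positives with U raised to 0.40
#'   (a strong U-rich signal, mirroring the pyrimidine richness of real
#'   IRES-positive segments).
#' @param plant_hairpin Insert a 24-base hairpin (10-bp stem, 4-base loop)
#'   at a random position in positive sequences.
#' @return Object of class `signal_config`.
#' @export
signal_config <- function(neg_freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                          pos_freqs = c(A = 0.18, C = 0.25, G = 0.17, U = 0.40),
                          plant_hairpin = FALSE) {
  for (f in list(neg_freqs, pos_freqs)) {
    if (!setequal(names(f), c("A", "C", "G", "U")) || any(f < 0) ||
        abs(sum(f) - 1) > 1e-8) {
      stop("config error: base frequencies must be named A/C/G/U and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(neg_freqs = neg_freqs[c("A", "C", "G", "U")],
                 pos_freqs = pos_freqs[c("A", "C", "G", "U")],
                 plant_hairpin = isTRUE(plant_hairpin)),
            class = "signal_config")
}

random_residues <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

plant_hairpin_in <- function(residues, stem = 10L, loop = 4L) {
  L <- nchar(residues)
  hp_len <- 2L * stem + loop
  if (L < hp_len + 2L) return(residues)
  arm <- paste(sample(c("A", "C", "G", "U"), stem, replace = TRUE), collapse = "")
  comp <- chartr("ACGU", "UGCA", arm)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  lp <- paste(sample(c("A", "C", "G", "U"), loop, replace = TRUE), collapse = "")
  pos <- sample.int(L - hp_len + 1L, 1L)
  paste0(substr(residues, 1L, pos - 1L), arm, lp, rc,
         substr(residues, pos + hp_len, L))
}

#' Generate a synthetic bicistronic-assay fixture
#'
#' Emulates the structure of the published training table: fixed-length
#' inserts (default 173 bases), an imbalanced class ratio (choose
#' `n_pos`/`n_neg` near 1:8.6 for realism), U-rich positives, activity
#' scores that reproduce the intended labels under [assign_labels()]
#' (negatives in (206, 600), positives in (600, 50000), log-uniform), and
#' optionally rows that fail each quality filter.
#'
#' @param n_pos,n_neg Numbers of positive / negative records.
#' @param seq_length Insert length in bases (default 173).
#' @param signal A [signal_config()].
#' @param rng_seed Integer seed; the output is fully reproducible.
#' @param include_failing Add records violating the category, splicing and
#'   promoter filters (3 extra rows), for filter tests.
#' @return Assay table data.frame with a `planted_label` column recording
#'   the generating class (labels themselves are left to [assign_labels()]).
#' @export
generate_synthetic_assay <- function(n_pos, n_neg, seq_length = 173L,
                                     signal = signal_config(),
                                     rng_seed = 1L,
                                     include_failing = FALSE) {
  stopifnot(inherits(signal, "signal_config"))
  seq_length <- as.integer(seq_length)
  if (seq_length < 20L) stop("seq_length must be >= 20", call. = FALSE)
  if (n_pos < 0 || n_neg < 0) stop("n_pos, n_neg must be >= 0", call. = FALSE)

  with_seed(rng_seed, {
    mk <- function(n, freqs, positive) {
      if (n == 0L) return(NULL)
      seqs <- vapply(seq_len(n), function(i) {
        s <- random_residues(seq_length, freqs)
        if (positive && signal$plant_hairpin) s <- plant_hairpin_in(s)
        s
      }, character(1))
      act <- if (positive) {
        exp(stats::runif(n, log(601), log(50000)))
      } else {
        stats::runif(n, 206, 599)
      }
      data.frame(
        id = sprintf("%s%04d", if (positive) "pos" else "neg", seq_len(n)),
        sequence = seqs,
        category = sample(NATIVE_CATEGORIES, n, replace = TRUE),
        ires_activity = act,
        splicing_score = pmax(stats::rnorm(n, 0, 1), -2.4),
        promoter_activity = stats::runif(n, 0, 0.19),
        planted_label = if (positive) "IRES" else "nonIRES",
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(mk(n_pos, signal$pos_freqs, TRUE),
                 mk(n_neg, signal$neg_freqs, FALSE))
    if (include_failing) {
      fail <- data.frame(
        id = c("fail_cat", "fail_splice", "fail_prom"),
        sequence = vapply(1:3, function(i)
          random_residues(seq_length, signal$neg_freqs), character(1)),
        category = c("synthetic_mutant", NATIVE_CATEGORIES[1], NATIVE_CATEGORIES[1]),
        ires_activity = c(300, 300, 300),
        splicing_score = c(0, -3.1, 0),
        promoter_activity = c(0.1, 0.1, 0.35),
        planted_label = "nonIRES",
        stringsAsFactors = FALSE
      )
      out <- rbind(out, fail)
    }
    rownames(out) <- NULL
    out
  })
}

#' Convert an assay table's sequences to rna_sequence records
#'
#' @param records Assay table data.frame.
#' @return List of [rna_sequence()].
#' @export
assay_sequences <- function(records) {
  check_assay_table(records)
  lapply(seq_len(nrow(records)), function(i) {
    rna_sequence(records$id[i], records$sequence[i])
  })
}
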