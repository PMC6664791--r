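#' Kmer feature space
#'
#' Defines the ordered vocabulary of kmer words used for feature extraction:
#' for each k in `min_k:max_k`, all `4^k` words over A/C/G/U in lexicographic
#' order with `A < C < G < U`. The default range 1..4 yields 4 + 16 + 64 +
#' 256 = 340 words; this ordering is fixed so that feature vectors computed
#' with the same configuration always align.
#'
#' @param min_k,max_k Integer bounds of the k range, within `[1, 8]`.
#' @return An object of class `kmer_space` with fields `min_k`, `max_k` and
#'   the ordered character vector `words`.
#' @export
kmer_space <- function(min_k = 1L, max_k = 4L) {
  min_k <- as.integer(min_k); max_k <- as.integer(max_k)
  if (is.na(min_k) || is.na(max_k) || min_k < 1L || max_k > 8L || min_k > max_k) {
    stop("kmer_space: require 1 <= min_k <= max_k <= 8", call. = FALSE)
  }
  words <- unlist(lapply(min_k:max_k, kmer_words), use.names = FALSE)
  structure(list(min_k = min_k, max_k = max_k, words = words),
            class = "kmer_space")
}

# all 4^k words of length k, lexicographic in A < C < G < U
kmer_words <- function(k) {
  alph <- c("A", "C", "G", "U")
  grids <- rev(lapply(seq_len(k), function(i) alph))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reversed input + reversed
  # column paste gives lexicographic order
  do.call(paste0, rev(g))
}

#' Enumerate the kmer vocabulary
#'
#' @param space A [kmer_space()].
#' @return Ordered character vector of all words in the space.
#' @export
enumerate_kmers <- function(space = kmer_space()) {
  stopifnot(inherits(space, "kmer_space"))
  space$words
}

#' Local window configuration
#'
#' Windows of `window` bases starting every `step` bases from the 5' end
#' (1-based starts 1, 1+step, 1+2*step, ...). The defaults (20-base windows,
#' 10-base step, i.e. 10-base overlap) follow the published windowing. With
#' `partial_final_window = TRUE` one trailing truncated window (length at
#' least `max_k` of the kmer space) is appended; local features are named
#' `word_start`, e.g. `"U_121"`.
#'
#' @param window Window length in bases (default 20).
#' @param step Step between window starts in bases (default 10).
#' @param partial_final_window Include a final truncated window?
#' @return An object of class `local_window_config`.
#' @export
local_window_config <- function(window = 20L, step = 10L,
                                partial_final_window = FALSE) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || is.na(step) || step < 1L || step > window) {
    stop("local_window_config: require 0 < step <= window", call. = FALSE)
  }
  structure(list(window = window, step = step,
                 partial_final_window = isTRUE(partial_final_window)),
            class = "local_window_config")
}

# count occurrences (with overlap) of every word of each k in `space` within
# `chars`; windows containing a non-ACGU character contribute zero for the
# affected positions. Returns counts in space$words order.
count_kmers <- function(residues, space) {
  rs <- tryCatch(Biostrings::RNAString(residues), error = function(e) NULL)
  unlist(lapply(space$min_k:space$max_k, function(k) {
    if (!is.null(rs) && nchar(residues) >= k) {
      # Biostrings enumerates ACGU words lexicographically; exact-match
      # counting ignores windows containing ambiguity codes.
      as.numeric(Biostrings::oligonucleotideFrequency(rs, width = k))
    } else {
      numeric(4^k)
    }
  }), use.names = FALSE)
}

#' Global kmer frequency features
#'
#' Counts every word of the kmer space over the entire sequence (counting
#' overlaps) and divides each count by the sequence length `L` (not by the
#' number of kmer positions `L - k + 1`). For the default 1..4 space the
#' result has exactly 340 entries named by the word itself.
#'
#' @param seq An [rna_sequence()].
#' @param space A [kmer_space()].
#' @return Named numeric vector of frequencies, in the space's fixed order.
#' @export
global_kmer_features <- function(seq, space = kmer_space()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(space, "kmer_space"))
  if (seq$length < space$max_k) {
    stop(sprintf("degenerate input: sequence '%s' shorter than max_k = %d",
                 seq$id, space$max_k), call. = FALSE)
  }
  counts <- count_kmers(seq$residues, space)
  stats::setNames(counts / seq$length, space$words)
}

# 1-based window start positions for a sequence of length L
window_starts <- function(L, cfg, max_k = 4L) {
  starts <- if (L >= cfg$window) seq(1L, L - cfg$window + 1L, by = cfg$step) else integer(0)
  if (cfg$partial_final_window) {
    nxt <- if (length(starts)) starts[length(starts)] + cfg$step else 1L
    if (nxt <= L && (L - nxt + 1L) >= max_k) starts <- c(starts, nxt)
  }
  starts
}

#' Local (windowed) kmer frequency features
#'
#' Counts the kmer vocabulary inside each window and divides by that
#' window's actual length. Feature names are `word_start` with the 1-based
#' window start, e.g. `"U_121"`. For a 173-base sequence under the default
#' configuration this yields 16 full windows (5440 features), or 17 windows
#' (5780 features, last start 161) when the truncated final window is
#' enabled.
#'
#' @inheritParams global_kmer_features
#' @param cfg A [local_window_config()].
#' @return Named numeric vector, windows in start order, each using the
#'   space's word order.
#' @export
local_kmer_features <- function(seq, space = kmer_space(),
                                cfg = local_window_config()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(space, "kmer_space"),
            inherits(cfg, "local_window_config"))
  if (seq$length < cfg$window && !cfg$partial_final_window) {
    stop(sprintf("degenerate input: sequence '%s' (%d nt) shorter than window %d",
                 seq$id, seq$length, cfg$window), call. = FALSE)
  }
  starts <- window_starts(seq$length, cfg, space$max_k)
  if (length(starts) == 0L) {
    stop(sprintf("degenerate input: no admissible window for sequence '%s'",
                 seq$id), call. = FALSE)
  }
  vals <- lapply(starts, function(s) {
    e <- min(s + cfg$window - 1L, seq$length)
    count_kmers(substr(seq$residues, s, e), space) / (e - s + 1L)
  })
  names_all <- unlist(lapply(starts, function(s) paste0(space$words, "_", s)),
                      use.names = FALSE)
  stats::setNames(unlist(vals, use.names = FALSE), names_all)
}
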