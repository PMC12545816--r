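# Canonical G-quadruplex pattern scan (presence/absence), G3L1-7 / G2L1-4
# style: four G-runs separated by three loops of bounded length.

#' Scan a sequence for canonical G-quadruplex-forming patterns
#'
#' A match is any combination of four maximal G-runs of length at least
#' `g_group` whose three intervening loops (gaps between the chosen runs)
#' have lengths within `loop_range`, with total span at most `max_span`.
#' Both strands are scanned by default (C-patterns on the reverse strand are
#' reported in forward coordinates).
#'
#' @param sequence Sequence string over `{A,C,G,T,N}`.
#' @param g_group Minimum G-run length (2 or 3).
#' @param loop_range Length-2 integer vector of allowed loop lengths
#'   (e.g. `c(1, 7)` with `g_group = 3`, `c(1, 4)` with `g_group = 2`).
#' @param max_span Maximum match span in bp (default 45).
#' @param both_strands Scan the reverse complement too.
#' @return Tibble of matches: 0-based half-open `start`/`end`, `strand`,
#'   `g_group`, `loop1`, `loop2`, `loop3`.
#' @export
scan_gquad <- function(sequence, g_group = 3L, loop_range = c(1L, 7L),
                       max_span = 45L, both_strands = TRUE) {
  if (loop_range[1] < 1) stop("loop_range lower bound must be at least 1")
  sequence <- normalize_alphabet(sequence)
  out <- gquad_one_strand(sequence, g_group, loop_range, max_span)
  if (nrow(out) > 0) out$strand <- "+"
  if (both_strands) {
    L <- nchar(sequence)
    rc <- gquad_one_strand(revcomp(sequence), g_group, loop_range, max_span)
    if (nrow(rc) > 0) {
      tmp <- L - rc$end
      rc$end <- L - rc$start
      rc$start <- tmp
      rc$strand <- "-"
      out <- dplyr::bind_rows(out, rc)
    }
  }
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), g_group = integer(),
                          loop1 = integer(), loop2 = integer(),
                          loop3 = integer()))
  }
  dplyr::arrange(out[, c("start", "end", "strand", "g_group",
                         "loop1", "loop2", "loop3")],
                 .data$start, .data$end, .data$strand)
}

gquad_one_strand <- function(sequence, g_group, loop_range, max_span) {
  m <- gregexpr(paste0("G{", g_group, ",}"), sequence)[[1]]
  rows <- list()
  if (m[1] != -1) {
    starts <- as.integer(m) - 1L # 0-based
    lens <- attr(m, "match.length")
    ends <- starts + lens
    nr <- length(starts)
    if (nr >= 4) {
      for (i1 in 1:(nr - 3)) {
        for (i2 in (i1 + 1):(nr - 2)) {
          l1 <- starts[i2] - ends[i1]
          if (l1 < loop_range[1] || l1 > loop_range[2]) next
          for (i3 in (i2 + 1):(nr - 1)) {
            l2 <- starts[i3] - ends[i2]
            if (l2 < loop_range[1] || l2 > loop_range[2]) next
            for (i4 in (i3 + 1):nr) {
              l3 <- starts[i4] - ends[i3]
              if (l3 < loop_range[1] || l3 > loop_range[2]) next
              if (ends[i4] - starts[i1] > max_span) next
              rows[[length(rows) + 1]] <- tibble::tibble(
                start = starts[i1], end = ends[i4],
                g_group = as.integer(g_group),
                loop1 = l1, loop2 = l2, loop3 = l3)
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          g_group = integer(), loop1 = integer(),
                          loop2 = integer(), loop3 = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Presence/absence G-quadruplex summary per sequence
#'
#' @param seqs Named character vector of sequences (e.g. CNS sequences).
#' @inheritParams scan_gquad
#' @return Tibble per sequence: `n_matches`, `present`.
#' @export
scan_gquad_set <- function(seqs, g_group = 3L, loop_range = c(1L, 7L),
                           max_span = 45L, both_strands = TRUE) {
  purrr::map_dfr(seq_along(seqs), function(i) {
    hits <- scan_gquad(seqs[[i]], g_group, loop_range, max_span, both_strands)
    tibble::tibble(
      seq_id = names(seqs)[i] %||% paste0("seq", i),
      g_group = as.integer(g_group),
      n_matches = nrow(hits),
      present = nrow(hits) > 0
    )
  })
}
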