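#' One step of the uncovering process
#'
#' Teaches fresh ensembles on the panel minus the already-removed organisms,
#' recognizes the reference organism's image with each, and returns the
#' per-mode reports.  Removal is driven solely by the main recognition
#' system — the ensemble taught on concatenated images: `removed_after` is
#' the set it recognized, or its best sub-threshold organism when
#' `allow_subthreshold` is on and nothing reaches the threshold.
#' Single-gene ensembles are reported for comparison only.
#'
#' @param panel An [organism_panel()].
#' @param removed Latin names already removed from the teaching set (must
#'   include the current reference).
#' @param reference Latin name of the organism whose image is recognized.
#' @param modes Modes to teach and report; must include `"concat"`.
#' @param seed Base seed for the ensembles of this step (member seeds are
#'   derived from it; each mode gets its own offset).
#' @param threshold Recognition threshold (default 0.01).
#' @param allow_subthreshold Continue with the best sub-threshold organism
#'   when the main system recognizes nothing (used for bottom-up runs,
#'   where recognized similarities to bacteria fall below 0.01).
#' @param hyper,n_members Passed to [teach_ensemble()].
#' @return Object of class `uncover_step`: `step_label` (filled by
#'   [run_uncovering()]), `reference`, `teaching_set`, `reports` (named by
#'   mode), `removed_after`, `subthreshold_used`, `lost_recognition`.
#' @export
uncover_step <- function(panel, removed, reference, modes = "concat",
                         seed = 1L, threshold = 0.01,
                         allow_subthreshold = FALSE, hyper = list(),
                         n_members = 5L) {
  stopifnot("concat" %in% modes, reference %in% panel_names(panel))
  if (!reference %in% removed)
    stop("the reference organism must be in the removed set", call. = FALSE)
  teaching_set <- setdiff(panel_names(panel), removed)
  if (!length(teaching_set))
    stop("empty teaching set: nothing left to uncover", call. = FALSE)
  reports <- list()
  for (i in seq_along(modes)) {
    ens <- teach_ensemble(panel, exclude = removed, mode = modes[i],
                          base_seed = seed + 100L * (i - 1L),
                          hyper = hyper, n_members = n_members)
    reports[[modes[i]]] <- recognize(ens, panel[[reference]], threshold)
  }
  main <- reports[["concat"]]
  removed_after <- main$recognized
  subthreshold_used <- FALSE
  if (!length(removed_after) && allow_subthreshold) {
    removed_after <- main$below_threshold_top
    subthreshold_used <- TRUE
  }
  structure(list(step_label = NA_character_, reference = reference,
                 teaching_set = teaching_set, reports = reports,
                 removed_after = removed_after,
                 subthreshold_used = subthreshold_used,
                 lost_recognition = !length(removed_after)),
            class = "uncover_step")
}

step_foreground <- function(step) {
  main <- step$reports[["concat"]]
  if (!is.na(main$foreground)) main$foreground
  else if (step$subthreshold_used) step$removed_after[1L]
  else NA_character_
}

#' Run the iterative uncovering process
#'
#' Starting from a reference organism, repeatedly: teach ensembles on the
#' remaining organisms, recognize the reference image, and remove the
#' organisms recognized by the main (concatenated-image) system from the
#' teaching set.  When the main system loses recognition, the reference
#' switches to the earliest-recognized foreground organism not yet used as
#' a reference (a FIFO queue over foregrounds); the run halts when the
#' queue is empty or the teaching set is exhausted.  Homologous-position
#' fractions of every foreground against the apex (start) reference are
#' recorded for threshold-organism detection.
#'
#' @inheritParams uncover_step
#' @param start_reference Latin name of the apex organism.
#' @param direction `"top_down"` or `"bottom_up"` (labels the steps `1A`,
#'   `2A`, ... or `1B`, `2B`, ...).  `allow_subthreshold` defaults to
#'   `TRUE` for bottom-up runs and `FALSE` for top-down runs.
#' @param table Codon table used for the homologous-fraction bookkeeping.
#' @return Object of class `uncover_trace`: `direction`, `apex`, `steps`,
#'   `reference_history`, `foregrounds` (in visit order), `visited`
#'   (removal order), `homolog_fraction` (per foreground, vs apex),
#'   `switch_after` (indices of foregrounds that opened a new reference).
#' @export
run_uncovering <- function(panel, start_reference,
                           direction = c("top_down", "bottom_up"),
                           seed = 1L, threshold = 0.01,
                           modes = "concat",
                           allow_subthreshold = NULL,
                           hyper = list(), n_members = 5L,
                           table = codon_table()) {
  direction <- match.arg(direction)
  stopifnot(start_reference %in% panel_names(panel))
  if (is.null(allow_subthreshold))
    allow_subthreshold <- direction == "bottom_up"
  suffix <- if (direction == "top_down") "A" else "B"

  removed <- start_reference
  reference <- start_reference
  queue <- character()     # foregrounds awaiting their turn as reference
  used_refs <- start_reference
  steps <- list()
  foregrounds <- character()
  visited <- character()
  after_switch <- integer()  # foreground indices right after a switch
  step_no <- 0L
  just_switched <- FALSE

  repeat {
    teaching_set <- setdiff(panel_names(panel), removed)
    if (!length(teaching_set)) break
    step_no <- step_no + 1L
    step <- uncover_step(panel, removed, reference, modes = modes,
                         seed = seed + 1000L * (step_no - 1L),
                         threshold = threshold,
                         allow_subthreshold = allow_subthreshold,
                         hyper = hyper, n_members = n_members)
    step$step_label <- paste0(step_no, suffix)
    steps[[length(steps) + 1L]] <- step
    if (length(step$removed_after)) {
      removed <- c(removed, step$removed_after)
      visited <- c(visited, step$removed_after)
      fg <- step_foreground(step)
      foregrounds <- c(foregrounds, fg)
      queue <- c(queue, fg)
      if (just_switched) {
        after_switch <- c(after_switch, length(foregrounds))
        just_switched <- FALSE
      }
    } else {
      # main system lost recognition: switch reference via the FIFO queue
      next_ref <- setdiff(queue, used_refs)
      if (!length(next_ref)) break
      reference <- next_ref[1L]
      used_refs <- c(used_refs, reference)
      just_switched <- TRUE
    }
  }

  apex_seq <- fitted_sequence(panel[[start_reference]], panel_ref(panel),
                              "concat")
  homolog_fraction <- vapply(foregrounds, function(org) {
    cp <- count_positions(apex_seq,
                          fitted_sequence(panel[[org]], panel_ref(panel),
                                          "concat"),
                          table = table)
    cp$r / cp$total
  }, numeric(1))

  structure(list(direction = direction, apex = start_reference,
                 steps = steps, reference_history = used_refs,
                 foregrounds = foregrounds, visited = visited,
                 homolog_fraction = homolog_fraction,
                 switch_after = after_switch,
                 seed = seed, threshold = threshold),
            class = "uncover_trace")
}

#' @export
print.uncover_trace <- function(x, ...) {
  cat(sprintf("uncover_trace (%s) from %s: %d steps\n",
              x$direction, x$apex, length(x$steps)))
  for (s in x$steps) {
    main <- s$reports[["concat"]]
    what <- if (s$lost_recognition) "lost recognition"
            else paste(s$removed_after, collapse = ", ")
    cat(sprintf("  %-4s ref=%-25s teach=%2d  -> %s%s\n", s$step_label,
                s$reference, length(s$teaching_set), what,
                if (s$subthreshold_used) " (sub-threshold)" else ""))
  }
  invisible(x)
}

#' Detect threshold organisms along a trace
#'
#' A top-down trace is scanned for the organism after which the
#' homologous-position fraction against the apex drops below `low_frac`
#' (default 25 %): the marker (`**`) lands on the last foreground at or
#' above `low_frac` before the first one below it.  A bottom-up trace gets
#' its marker (`***`) on the last foreground at or below `high_frac`
#' (default 50 %) before the fraction first exceeds it.  The first
#' foreground recognized after each reference switch is marked `*`.
#'
#' @param trace An [run_uncovering()] trace.
#' @param low_frac,high_frac Fraction cut-offs for the top-down and
#'   bottom-up rules.
#' @return Data frame with columns `organism`, `marker` (`*`, `**`, `***`);
#'   zero rows when the trace has no markers.
#' @export
detect_threshold_organisms <- function(trace, low_frac = 0.25,
                                       high_frac = 0.50) {
  out <- data.frame(organism = character(), marker = character(),
                    stringsAsFactors = FALSE)
  fr <- trace$homolog_fraction
  fg <- trace$foregrounds
  if (!length(fg)) return(out)
  for (i in trace$switch_after)
    out <- rbind(out, data.frame(organism = fg[i], marker = "*"))
  if (trace$direction == "top_down") {
    below <- which(fr < low_frac)
    if (length(below) && below[1L] > 1L) {
      prior <- which(fr[seq_len(below[1L] - 1L)] >= low_frac)
      if (length(prior))
        out <- rbind(out, data.frame(organism = fg[max(prior)],
                                     marker = "**"))
    }
  } else {
    above <- which(fr > high_frac)
    if (length(above) && above[1L] > 1L) {
      prior <- which(fr[seq_len(above[1L] - 1L)] <= high_frac)
      if (length(prior))
        out <- rbind(out, data.frame(organism = fg[max(prior)],
                                     marker = "***"))
    }
  }
  out
}

step_backgrounds <- function(step) {
  main <- step$reports[["concat"]]
  main$background
}

#' Reconstruct the virtual line of inheritance
#'
#' Merges a top-down and a bottom-up trace over the same panel into one
#' ordered line: position 0 is the top apex, followed by the top-down
#' foregrounds in step order up to the credibility bound (by default the
#' step of the top-down threshold organism, where the homologous fraction
#' collapses); the bottom-up foregrounds are then appended in reverse,
#' from its threshold organism back to the bottom apex.  Background
#' organisms ride along in brackets with their step's foreground.
#'
#' @param top_trace,bottom_trace Top-down / bottom-up [run_uncovering()]
#'   traces over the same panel.
#' @param credibility_bound Number of leading top-down foregrounds to keep;
#'   `NULL` (default) keeps them through the top-down threshold organism,
#'   or all of them when no threshold organism is found.
#' @param low_frac,high_frac Passed to [detect_threshold_organisms()].
#' @return Object of class `virtual_line`: `line` (data frame `position`,
#'   `organism`, `role`, `marker`, `backgrounds`), `unplaced` (panel
#'   organisms on no position), `conflicts` (organisms that two positions
#'   claimed; first placement kept).
#' @export
build_virtual_line <- function(top_trace, bottom_trace,
                               credibility_bound = NULL,
                               low_frac = 0.25, high_frac = 0.50) {
  stopifnot(top_trace$direction == "top_down",
            bottom_trace$direction == "bottom_up")
  top_marks <- detect_threshold_organisms(top_trace, low_frac, high_frac)
  bot_marks <- detect_threshold_organisms(bottom_trace, low_frac, high_frac)
  marker_of <- function(org) {
    m <- c(top_marks$marker[top_marks$organism == org],
           bot_marks$marker[bot_marks$organism == org])
    if (length(m)) paste(m, collapse = "") else ""
  }

  if (is.null(credibility_bound)) {
    thr <- top_marks$organism[top_marks$marker == "**"]
    credibility_bound <- if (length(thr))
      match(thr[1L], top_trace$foregrounds) else length(top_trace$foregrounds)
  }
  top_keep <- seq_len(min(credibility_bound, length(top_trace$foregrounds)))

  bot_thr <- bot_marks$organism[bot_marks$marker == "***"]
  bot_stop <- if (length(bot_thr)) match(bot_thr[1L], bottom_trace$foregrounds)
              else length(bottom_trace$foregrounds)

  fg_steps <- function(trace) {
    keep <- !vapply(trace$steps, function(s) s$lost_recognition, logical(1))
    trace$steps[keep]
  }
  top_steps <- fg_steps(top_trace)
  bot_steps <- fg_steps(bottom_trace)

  entries <- list(list(organism = top_trace$apex, role = "apex",
                       backgrounds = character()))
  for (i in top_keep)
    entries[[length(entries) + 1L]] <-
      list(organism = top_trace$foregrounds[i], role = "foreground",
           backgrounds = step_backgrounds(top_steps[[i]]))
  for (i in rev(seq_len(bot_stop)))
    entries[[length(entries) + 1L]] <-
      list(organism = bottom_trace$foregrounds[i], role = "foreground",
           backgrounds = setdiff(step_backgrounds(bot_steps[[i]]),
                                 bottom_trace$foregrounds))
  entries[[length(entries) + 1L]] <-
    list(organism = bottom_trace$apex, role = "apex",
         backgrounds = character())

  placed <- character()
  conflicts <- character()
  rows <- list()
  for (pos in seq_along(entries)) {
    e <- entries[[pos]]
    orgs <- c(e$organism, e$backgrounds)
    dup <- intersect(orgs, placed)
    conflicts <- c(conflicts, dup)
    orgs <- setdiff(orgs, placed)
    if (!e$organism %in% orgs) next  # whole entry already placed
    placed <- c(placed, orgs)
    rows[[length(rows) + 1L]] <-
      data.frame(position = length(rows),
                 organism = e$organism, role = e$role,
                 marker = marker_of(e$organism),
                 backgrounds = paste(setdiff(orgs, e$organism),
                                     collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  line <- do.call(rbind, rows)
  panel_orgs <- unique(c(top_trace$apex, top_trace$visited,
                         bottom_trace$apex, bottom_trace$visited))
  structure(list(line = line,
                 unplaced = setdiff(panel_orgs, placed),
                 conflicts = unique(conflicts)),
            class = "virtual_line")
}

#' @export
print.virtual_line <- function(x, ...) {
  cat("virtual line of inheritance:\n")
  for (i in seq_len(nrow(x$line))) {
    row <- x$line[i, ]
    bg <- if (nzchar(row$backgrounds))
      sprintf(" (%s)", gsub(";", ", ", row$backgrounds)) else ""
    cat(sprintf("  %2d  %s%s%s\n", row$position, row$organism,
                if (nzchar(row$marker)) paste0(" ", row$marker) else "", bg))
  }
  if (length(x$unplaced))
    cat("unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  if (length(x$conflicts))
    cat("conflicting placements:", paste(x$conflicts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of rooted binary trees on n labelled leaves
#'
#' The double factorial `(2n - 3)!!`, computed exactly with a small
#' base-10000 big-integer multiply (the count for 32 taxa has 43 digits,
#' beyond double precision).
#'
#' @param n Number of leaves, at least 2.
#' @return The exact count as a decimal string.
#' @examples
#' count_rooted_trees(4)  # "15"
#' @export
count_rooted_trees <- function(n) {
  stopifnot(length(n) == 1L)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2", call. = FALSE)
  digits <- c(1L)  # little-endian limbs, base 1e4
  for (f in if (n > 2L) seq(3L, 2L * n - 3L, by = 2L) else integer()) {
    carry <- 0
    for (i in seq_along(digits)) {
      v <- digits[i] * f + carry
      digits[i] <- v %% 10000L
      carry <- v %/% 10000L
    }
    while (carry > 0) {
      digits <- c(digits, carry %% 10000L)
      carry <- carry %/% 10000L
    }
  }
  paste0(digits[length(digits)],
         paste(sprintf("%04d", rev(digits[-length(digits)])), collapse = ""))
}
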