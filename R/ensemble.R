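#' Organism panel
#'
#' A panel is the ordered set of organisms under study.  Organisms are kept
#' sorted alphabetically by Latin name (C-locale radix order) — this fixes
#' the output-neuron order of every network taught from the panel, so label
#' order never depends on input file order.
#'
#' @param records List of [organism_record()] objects.
#' @param ref A [reference_lengths()] shared by the panel.
#' @return Object of class `organism_panel`: named list of records (names =
#'   Latin names) with attribute `ref`.
#' @export
organism_panel <- function(records, ref = reference_lengths()) {
  stopifnot(length(records) >= 1L)
  latin <- vapply(records, function(r) r$latin_name, character(1))
  if (anyDuplicated(latin))
    stop("duplicate Latin names in panel: ",
         paste(unique(latin[duplicated(latin)]), collapse = ", "),
         call. = FALSE)
  ord <- order(latin, method = "radix")
  records <- setNames(records[ord], latin[ord])
  structure(records, ref = ref, class = "organism_panel")
}

panel_ref <- function(panel) attr(panel, "ref")

panel_names <- function(panel) names(panel)

#' @export
print.organism_panel <- function(x, ...) {
  ref <- panel_ref(x)
  cat(sprintf("organism_panel: %d organisms, reference lengths %d + %d\n",
              length(x), ref$cytb_len, ref$coi_len))
  for (r in x) cat(sprintf("  %s (%s)\n", r$common_name, r$latin_name))
  invisible(x)
}

mode_input_size <- function(mode, ref) {
  5L * switch(mode,
              concat = ref$cytb_len + ref$coi_len,
              cytb = ref$cytb_len,
              coi = ref$coi_len)
}

default_hyper <- function(mode) {
  if (mode == "concat") list(learning_rate = 0.07, momentum = 0.07)
  else list(learning_rate = 0.3, momentum = 0.1)
}

#' Teach an ensemble of networks on a panel
#'
#' Builds genetic images for every panel organism not in `exclude`, then
#' trains `n_members` independently initialised networks (seeds
#' `base_seed + 0 ... + n_members - 1`) to the target RMSE (default 0.01).
#' Hyperparameter defaults depend on the mode: learning rate/momentum
#' 0.07/0.07 for concatenated images, 0.3/0.1 for single-gene images.
#'
#' @param panel An [organism_panel()].
#' @param exclude Latin names left out of the teaching set (typically the
#'   organism whose image will be recognized).
#' @param mode `"concat"`, `"cytb"` or `"coi"`.
#' @param base_seed Integer; member `i` uses seed `base_seed + i - 1`.
#' @param hyper Named list overriding [mlp_config()] fields
#'   (`learning_rate`, `momentum`, `target_rmse`, `max_epochs`, `n_hidden`,
#'   `shuffle`).
#' @param n_members Ensemble size (default 5).
#' @return Object of class `recognition_ensemble`: `mode`, `members` (list
#'   of trained `mlp_model`s), `teaching_set` (Latin names, canonical
#'   order), `ref`, `base_seed`, and per-member `epochs`.
#' @export
teach_ensemble <- function(panel, exclude = character(),
                           mode = c("concat", "cytb", "coi"),
                           base_seed = 1L, hyper = list(), n_members = 5L) {
  mode <- match.arg(mode)
  teaching_set <- setdiff(panel_names(panel), exclude)
  if (length(teaching_set) < 1L)
    stop("empty teaching set: every panel organism is excluded", call. = FALSE)
  ref <- panel_ref(panel)
  images <- lapply(panel[teaching_set], build_genetic_image, ref = ref,
                   mode = mode)
  X <- do.call(rbind, lapply(images, function(im) as.numeric(im$bits)))
  dup <- duplicated(X) | duplicated(X, fromLast = TRUE)
  if (any(dup))
    stop("teaching images are not distinct: ",
         paste(teaching_set[dup], collapse = ", "),
         " share identical genetic images; the one-hot teaching task is ",
         "unrealizable", call. = FALSE)
  k <- length(teaching_set)
  n <- mode_input_size(mode, ref)
  targets <- one_hot_targets(teaching_set, teaching_set)
  hy <- utils::modifyList(default_hyper(mode), hyper)
  members <- vector("list", n_members)
  epochs <- integer(n_members)
  for (i in seq_len(n_members)) {
    seed_i <- base_seed + i - 1L
    cfg <- do.call(mlp_config, c(list(n_inputs = n, n_outputs = k,
                                      seed = seed_i), hy))
    model <- init_mlp(cfg, label_order = teaching_set)
    model <- tryCatch(train_online(model, X, targets),
                      genimage_nonconvergence = function(e)
                        stop(sprintf("ensemble member %d (seed %d): %s",
                                     i, seed_i, conditionMessage(e)),
                             call. = FALSE))
    epochs[i] <- attr(model, "epochs")
    members[[i]] <- model
  }
  structure(list(mode = mode, members = members, teaching_set = teaching_set,
                 ref = ref, base_seed = base_seed, epochs = epochs),
            class = "recognition_ensemble")
}

#' Recognize a genetic image with an ensemble
#'
#' Evaluates every member on the query image and averages the activations
#' per teaching-set organism.  Organisms with average at or above the
#' recognition threshold (default 0.01) are "recognized", sorted by
#' descending average (ties broken lexicographically by Latin name); the
#' first is the foreground genetic image and the rest are background
#' images.  When nothing reaches the threshold the query is unrecognized
#' and `below_threshold_top` carries the best sub-threshold organism.
#'
#' @param ensemble A [teach_ensemble()] result.
#' @param query A `genetic_image` in the ensemble's mode, or an
#'   [organism_record()] (encoded automatically).
#' @param threshold Recognition threshold in `[0, 1]` (default 0.01).
#' @return Object of class `recognition_report`: `query_id`, `mode`,
#'   `averages` (named, descending), `threshold`, `recognized`,
#'   `foreground`, `background`, `below_threshold_top`.
#' @export
recognize <- function(ensemble, query, threshold = 0.01) {
  if (inherits(query, "organism_record"))
    query <- build_genetic_image(query, ensemble$ref, ensemble$mode)
  if (!identical(query$mode, ensemble$mode))
    stop(sprintf("query mode '%s' does not match ensemble mode '%s'",
                 query$mode, ensemble$mode), call. = FALSE)
  n <- mode_input_size(ensemble$mode, ensemble$ref)
  if (length(query$bits) != n)
    stop("query image size does not match ensemble input size", call. = FALSE)
  acts <- vapply(ensemble$members,
                 function(m) mlp_forward(m, query$bits),
                 numeric(length(ensemble$teaching_set)))
  averages <- rowMeans(matrix(acts, nrow = length(ensemble$teaching_set),
                              dimnames = list(ensemble$teaching_set, NULL)))
  ord <- order(-averages, names(averages), method = "radix")
  averages <- averages[ord]
  recognized <- names(averages)[averages >= threshold]
  structure(list(query_id = query$organism_id, mode = ensemble$mode,
                 averages = averages, threshold = threshold,
                 recognized = recognized,
                 foreground = if (length(recognized)) recognized[1L] else NA_character_,
                 background = if (length(recognized) > 1L) recognized[-1L] else character(),
                 below_threshold_top = if (length(recognized)) NA_character_
                                       else names(averages)[1L]),
            class = "recognition_report")
}

#' @export
print.recognition_report <- function(x, ...) {
  cat(sprintf("recognition of '%s' (%s images, threshold %g)\n",
              x$query_id, x$mode, x$threshold))
  if (length(x$recognized)) {
    for (org in x$recognized) {
      role <- if (org == x$foreground) "foreground" else "background"
      cat(sprintf("  %-30s %.4f  %s\n", org, x$averages[org], role))
    }
  } else {
    cat(sprintf("  unrecognized (best: %s at %.4f)\n",
                x$below_threshold_top, x$averages[1L]))
  }
  invisible(x)
}
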