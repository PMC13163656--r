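#' Read a protein FASTA file
#'
#' Standard multi-record FASTA parsing (via Biostrings), preserving record
#' order, uppercasing sequences, and rejecting empty records.  The record
#' id is the first whitespace-delimited token of the header; the rest is
#' the description.
#'
#' @param path FASTA file.
#' @return Data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("[\r ]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records Data frame with `id`, `description`, `sequence` (as from
#'   [read_fasta()]), or an [organism_panel()] (written as
#'   `<latin>_cytb` / `<latin>_coi` records).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "organism_panel")) {
    records <- do.call(rbind, lapply(records, function(r)
      data.frame(id = paste0(gsub(" ", "_", r$latin_name), c("_cytb", "_coi")),
                 description = r$common_name,
                 sequence = c(r$cytb_seq, r$coi_seq),
                 stringsAsFactors = FALSE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    seq <- records$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con)
  }
  invisible(path)
}

#' Load a panel from a YAML configuration and FASTA files
#'
#' The YAML file maps organisms to FASTA records:
#' ```yaml
#' reference_lengths: {cytb: 380, coi: 513}
#' code_table: "1"
#' organisms:
#'   - {common_name: Human, latin_name: Homo sapiens,
#'      cytb_record_id: HS_cytb, coi_record_id: HS_coi}
#' ```
#' Record ids must resolve uniquely across the supplied FASTA files;
#' organisms come back in canonical (Latin-name) order regardless of the
#' order in the config.
#'
#' @param config_path YAML panel configuration.
#' @param fasta_paths One or more FASTA files holding the sequences.
#' @return An [organism_panel()] with attribute `code_table` (the
#'   configured genetic-code id, default `"1"`).
#' @export
load_panel <- function(config_path, fasta_paths) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$organisms) || !length(cfg$organisms))
    stop("panel config lists no organisms", call. = FALSE)
  fa <- do.call(rbind, lapply(fasta_paths, read_fasta))
  if (anyDuplicated(fa$id))
    stop("duplicate FASTA record ids: ",
         paste(unique(fa$id[duplicated(fa$id)]), collapse = ", "),
         call. = FALSE)
  seq_of <- function(rid, org) {
    hit <- fa$sequence[fa$id == rid]
    if (length(hit) != 1L)
      stop(sprintf("record id '%s' for organism '%s' not found", rid, org),
           call. = FALSE)
    hit
  }
  records <- lapply(cfg$organisms, function(o) {
    organism_record(o$common_name, o$latin_name,
                    seq_of(o$cytb_record_id, o$latin_name),
                    seq_of(o$coi_record_id, o$latin_name))
  })
  ref <- if (!is.null(cfg$reference_lengths))
    reference_lengths(cfg$reference_lengths$cytb, cfg$reference_lengths$coi)
  else reference_lengths()
  panel <- organism_panel(records, ref)
  attr(panel, "code_table") <- as.character(cfg$code_table %||% "1")
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write recognition / uncovering results to files
#'
#' A `recognition_report` becomes a TSV (`organism`, `average`,
#' `recognized`, `role`); an `uncover_trace` becomes a replayable JSON
#' file (see [write_trace()]).
#'
#' @param x A `recognition_report` or `uncover_trace`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the query id or trace direction.
#' @return Paths of the files written, invisibly.
#' @export
write_reports <- function(x, dir, stem = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "recognition_report")) {
    stem <- stem %||% gsub("[^A-Za-z0-9]+", "_", x$query_id)
    path <- file.path(dir, paste0(stem, ".tsv"))
    df <- data.frame(organism = names(x$averages),
                     average = sprintf("%.6f", unname(x$averages)),
                     recognized = names(x$averages) %in% x$recognized,
                     role = ifelse(names(x$averages) %in% x$foreground,
                                   "foreground",
                                   ifelse(names(x$averages) %in% x$background,
                                          "background", "")),
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (inherits(x, "uncover_trace")) {
    stem <- stem %||% paste0("trace_", x$direction)
    path <- file.path(dir, paste0(stem, ".json"))
    write_trace(x, path)
    return(invisible(path))
  }
  stop("no writer for class ", paste(class(x), collapse = "/"), call. = FALSE)
}

report_to_list <- function(r) {
  list(query_id = r$query_id, mode = r$mode,
       organisms = names(r$averages), averages = unname(r$averages),
       threshold = r$threshold, recognized = r$recognized,
       foreground = r$foreground, background = r$background,
       below_threshold_top = r$below_threshold_top)
}

list_to_report <- function(l) {
  structure(list(query_id = l$query_id, mode = l$mode,
                 averages = setNames(as.numeric(l$averages),
                                     as.character(l$organisms)),
                 threshold = l$threshold,
                 recognized = as.character(l$recognized %||% character()),
                 foreground = l$foreground %||% NA_character_,
                 background = as.character(l$background %||% character()),
                 below_threshold_top = l$below_threshold_top %||% NA_character_),
            class = "recognition_report")
}

#' Serialize / restore an uncovering trace as JSON
#'
#' The JSON carries every step (teaching set, per-mode averages, removals,
#' sub-threshold flags) plus the base seed, so a trace can be reloaded or
#' the run replayed exactly.
#'
#' @param trace An `uncover_trace`.
#' @param path JSON file.
#' @return `path` invisibly; [read_trace()] returns the restored trace.
#' @export
write_trace <- function(trace, path) {
  obj <- list(format = "genimage-trace/1",
              direction = trace$direction, apex = trace$apex,
              seed = trace$seed, threshold = trace$threshold,
              reference_history = trace$reference_history,
              foregrounds = trace$foregrounds, visited = trace$visited,
              homolog_fraction = as.list(trace$homolog_fraction),
              switch_after = trace$switch_after,
              steps = lapply(trace$steps, function(s)
                list(step_label = s$step_label, reference = s$reference,
                     teaching_set = s$teaching_set,
                     reports = lapply(s$reports, report_to_list),
                     removed_after = s$removed_after,
                     subthreshold_used = s$subthreshold_used,
                     lost_recognition = s$lost_recognition)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "genimage-trace/1"))
    stop("not a genimage trace file", call. = FALSE)
  chr <- function(x) as.character(unlist(x))
  steps <- lapply(obj$steps, function(s)
    structure(list(step_label = s$step_label, reference = s$reference,
                   teaching_set = chr(s$teaching_set),
                   reports = lapply(s$reports, list_to_report),
                   removed_after = chr(s$removed_after),
                   subthreshold_used = isTRUE(s$subthreshold_used),
                   lost_recognition = isTRUE(s$lost_recognition)),
              class = "uncover_step"))
  structure(list(direction = obj$direction, apex = obj$apex,
                 steps = steps,
                 reference_history = chr(obj$reference_history),
                 foregrounds = chr(obj$foregrounds),
                 visited = chr(obj$visited),
                 homolog_fraction = setNames(
                   as.numeric(unlist(obj$homolog_fraction)),
                   names(obj$homolog_fraction)),
                 switch_after = as.integer(unlist(obj$switch_after)),
                 seed = obj$seed, threshold = obj$threshold),
            class = "uncover_trace")
}
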