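#' Simulation configuration for synthetic panels
#'
#' Describes a panel of organisms derived from a common ancestor by
#' codon-level single-nucleotide substitutions.  Each proposed substitution
#' is a transition with odds `kappa : 1` against a random transversion,
#' reflecting the transition bias of molecular evolution; substitutions
#' that would create a stop codon are rejected and redrawn so every node
#' stays translatable at full length.
#'
#' @param cytb_codons,coi_codons Gene lengths in codons (both `>= 1`).
#' @param topology Either a string `"chain:N"` (a ladder of `N` organisms,
#'   each the child of the previous) or an integer parent vector `p` with
#'   `p[1] = NA` for the root and `p[i] < i` otherwise (an arbitrary tree).
#' @param subs_per_branch Substitutions on each branch (`>= 0`).
#' @param kappa Transition/transversion proposal odds, `>= 0`; `Inf` forces
#'   every substitution to be a transition.
#' @param table A [codon_table()] used for stop-codon avoidance and
#'   translation.
#' @param distinct_proteins Redraw a branch whose child's translated
#'   proteins coincide with an existing node's (default `TRUE`).  Biased
#'   transitions are frequently synonymous, and duplicated amino-acid
#'   images would make the one-hot teaching task unrealizable — the real
#'   study panels are pairwise distinct at the protein level.  Ignored
#'   when `subs_per_branch` is 0.
#' @param seed Integer seed; all panel randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(cytb_codons = 60L, coi_codons = 80L,
                       topology = "chain:8", subs_per_branch = 4L,
                       kappa = 3, table = codon_table(),
                       distinct_proteins = TRUE, seed = 1L) {
  stopifnot(cytb_codons >= 1L, coi_codons >= 1L, subs_per_branch >= 0L,
            kappa >= 0)
  parents <- parse_topology(topology)
  structure(list(cytb_codons = as.integer(cytb_codons),
                 coi_codons = as.integer(coi_codons),
                 parents = parents, subs_per_branch = as.integer(subs_per_branch),
                 kappa = kappa, table = table,
                 distinct_proteins = isTRUE(distinct_proteins),
                 seed = as.integer(seed)),
            class = "sim_config")
}

parse_topology <- function(topology) {
  if (is.character(topology)) {
    m <- regmatches(topology, regexec("^chain:([0-9]+)$", topology))[[1]]
    if (length(m) != 2L)
      stop("topology string must look like 'chain:N'", call. = FALSE)
    n <- as.integer(m[2])
    if (n < 2L) stop("chain needs at least 2 organisms", call. = FALSE)
    return(c(NA_integer_, seq_len(n - 1L)))
  }
  parents <- as.integer(topology)
  if (!is.na(parents[1L]) || length(parents) < 2L ||
      any(parents[-1L] >= seq_along(parents)[-1L], na.rm = TRUE) ||
      anyNA(parents[-1L]))
    stop("parent vector must have NA root first and p[i] < i", call. = FALSE)
  parents
}

#' Draw a random stop-free codon sequence
#'
#' Uniformly random sense codons for the root organism; reproducible given
#' the seed.
#'
#' @param n_codons Number of codons.
#' @param table A [codon_table()].
#' @param seed Integer seed.
#' @return Character vector of RNA codons with no stop codon.
#' @export
simulate_root <- function(n_codons, table = codon_table(), seed = 1L) {
  sense <- names(table$sense_codons)
  withr_seed(seed, sample(sense, n_codons, replace = TRUE))
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

transition_partner <- c(A = "G", G = "A", C = "U", U = "C")

#' Mutate a codon sequence along one branch
#'
#' Applies `n_subs` single-nucleotide substitutions at uniformly chosen
#' sites.  Each substitution is a transition with probability
#' `kappa / (kappa + 1)` (certainty for `kappa = Inf`), otherwise one of
#' the two transversions chosen uniformly; proposals creating a stop codon
#' are rejected and redrawn (bounded, with an explicit failure).
#'
#' @param codons Parent RNA codon vector (stop-free).
#' @param n_subs Number of substitutions.
#' @param kappa Transition/transversion proposal odds.
#' @param table A [codon_table()].
#' @param seed Integer seed.
#' @return List with `codons` (the child) and `subs`, a data frame with
#'   columns `site` (nucleotide index over the concatenated sequence),
#'   `from`, `to`, `transition`.  Replaying `subs` on the parent
#'   reproduces the child exactly.
#' @export
mutate_lineage <- function(codons, n_subs, kappa = 3, table = codon_table(),
                           seed = 1L) {
  stopifnot(n_subs >= 0, kappa >= 0)
  withr_seed(seed, {
    nt <- strsplit(paste(codons, collapse = ""), "")[[1]]
    subs <- vector("list", n_subs)
    p_ts <- if (is.infinite(kappa)) 1 else kappa / (kappa + 1)
    for (s in seq_len(n_subs)) {
      ok <- FALSE
      for (try in 1:100) {
        site <- sample.int(length(nt), 1L)
        from <- nt[site]
        ts <- stats::runif(1) < p_ts
        to <- if (ts) transition_partner[[from]]
              else sample(setdiff(c("A", "C", "G", "U"),
                                  c(from, transition_partner[[from]])), 1L)
        codon_idx <- (site - 1L) %/% 3L + 1L
        cand <- nt
        cand[site] <- to
        new_codon <- paste(cand[(3L * codon_idx - 2L):(3L * codon_idx)],
                           collapse = "")
        if (!new_codon %in% table$stop_codons) {
          nt <- cand
          subs[[s]] <- data.frame(site = site, from = from, to = to,
                                  transition = ts, stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place a substitution without creating a stop codon",
                    call. = FALSE)
    }
    list(codons = paste_codons(nt),
         subs = if (n_subs) do.call(rbind, subs)
                else data.frame(site = integer(), from = character(),
                                to = character(), transition = logical()))
  })
}

paste_codons <- function(nt) {
  apply(matrix(nt, nrow = 3L), 2L, paste, collapse = "")
}

translate_codons <- function(codons, table) {
  aa <- table$sense_codons[codons]
  if (anyNA(aa)) stop("stop codon encountered during translation", call. = FALSE)
  paste(aa, collapse = "")
}

#' Generate a synthetic organism panel with known ancestry
#'
#' Walks the configured topology from a random stop-free root, mutating
#' each branch with [mutate_lineage()] and translating every node's codons
#' into the cytochrome b and COI amino-acid sequences of one organism.
#' Node `i` is named `orgNN` (zero-padded, so the canonical alphabetical
#' panel order equals generation order on a chain).
#'
#' @param config A [sim_config()].
#' @return List with `panel` (an [organism_panel()] whose reference lengths
#'   equal the gene lengths) and `truth`, a per-node list carrying
#'   `parent`, `codons_cytb`, `codons_coi` and the branch substitution
#'   table.
#' @export
generate_panel <- function(config) {
  n <- length(config$parents)
  n_codons <- config$cytb_codons + config$coi_codons
  ids <- sprintf("org%02d", seq_len(n))
  truth <- vector("list", n)
  names(truth) <- ids
  codons <- vector("list", n)
  codons[[1L]] <- simulate_root(n_codons, config$table, config$seed)
  truth[[1L]] <- list(parent = NA_character_,
                      subs = NULL)
  protein_of <- function(cod) translate_codons(cod, config$table)
  seen <- protein_of(codons[[1L]])
  check_distinct <- config$distinct_proteins && config$subs_per_branch > 0L
  for (i in seq_len(n)[-1L]) {
    for (try in 0:49) {
      mut <- mutate_lineage(codons[[config$parents[i]]],
                            config$subs_per_branch, config$kappa,
                            config$table,
                            seed = config$seed + 7919L * i + 500009L * try)
      if (!check_distinct || !protein_of(mut$codons) %in% seen) break
      if (try == 49L)
        stop("could not generate a protein-distinct child after 50 draws; ",
             "increase subs_per_branch or sequence length", call. = FALSE)
    }
    codons[[i]] <- mut$codons
    seen <- c(seen, protein_of(mut$codons))
    truth[[i]] <- list(parent = ids[config$parents[i]], subs = mut$subs)
  }
  records <- lapply(seq_len(n), function(i) {
    cytb <- codons[[i]][seq_len(config$cytb_codons)]
    coi <- codons[[i]][config$cytb_codons + seq_len(config$coi_codons)]
    truth[[i]]$codons_cytb <<- cytb
    truth[[i]]$codons_coi <<- coi
    organism_record(common_name = ids[i], latin_name = ids[i],
                    cytb_seq = translate_codons(cytb, config$table),
                    coi_seq = translate_codons(coi, config$table))
  })
  panel <- organism_panel(records,
                          ref = reference_lengths(config$cytb_codons,
                                                  config$coi_codons))
  list(panel = panel, truth = truth)
}
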