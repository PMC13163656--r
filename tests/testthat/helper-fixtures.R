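# Shared fixtures, all built in code.

# a tiny hand-written panel: 4 organisms, 6 + 8 residue references
tiny_panel <- function() {
  organism_panel(list(
    organism_record("alpha", "Aus alphus",  "MACDEF", "MTTWYKLH"),
    organism_record("beta",  "Bus betus",   "MACDEY", "MTTWYKLQ"),
    organism_record("gamma", "Cus gammus",  "MGCDEF", "MTTWYRLH"),
    organism_record("delta", "Dus deltus",  "MACNEF", "MTVWYKLH")),
    ref = reference_lengths(6L, 8L))
}

# simulated chain panel at desk scale (for ensemble/uncovering tests)
sim_chain_panel <- function(n = 4, cytb = 15, coi = 15, subs = 3, kappa = 3,
                            seed = 42) {
  generate_panel(sim_config(cytb, coi, sprintf("chain:%d", n),
                            subs_per_branch = subs, kappa = kappa,
                            seed = seed))
}

# inversion count of a sequence relative to a reference ordering
count_inversions <- function(seqv, truth_order) {
  r <- match(seqv, truth_order)
  stopifnot(!anyNA(r))
  if (length(r) < 2L) return(0L)
  sum(outer(seq_along(r), seq_along(r), "<") & outer(r, r, ">"))
}

# independent brute-force position classifier used as the oracle for the
# semihomology module: works directly from Biostrings' genetic code,
# without any genimage codon machinery
oracle_classify <- function(aa1, aa2, table_id, tie_policy) {
  gc <- Biostrings::getGeneticCode(table_id)
  codons <- chartr("T", "U", names(gc))
  c1 <- codons[gc == aa1 & gc != "*"]
  c2 <- codons[gc == aa2 & gc != "*"]
  if (!length(c1) || !length(c2)) return("-")
  if (aa1 == aa2) return("R")
  split3 <- function(x) strsplit(x, "")[[1]]
  best <- 3L; ts1 <- FALSE; tv1 <- FALSE
  for (x in c1) for (y in c2) {
    xs <- split3(x); ys <- split3(y)
    d <- sum(xs != ys)
    best <- min(best, d)
    if (d == 1L) {
      i <- which(xs != ys)
      pur <- c("A", "G")
      if ((xs[i] %in% pur) == (ys[i] %in% pur)) ts1 <- TRUE else tv1 <- TRUE
    }
  }
  if (best != 1L) return("-")
  if (ts1 && tv1) return(if (tie_policy == "transition") "#" else "$")
  if (ts1) "#" else "$"
}
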