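#' Maximum parsimony tree search with fast bootstrap approximation
#'
#' Full workflow: (1) draw `B` bootstrap weight vectors; (2) search tree
#' space on the *original* alignment (candidate-set initialization, then
#' perturbation + SPR hill climbing), offering every qualifying tree to all
#' replicates via exact weighted-sum rescoring with an early-abort lower
#' bound; (3) stop after `n'` consecutive unsuccessful steps; (4) refine
#' each replicate's best tree under its own weights; (5) map split supports
#' onto the best tree and build a majority-rule consensus.
#'
#' @param x an `mp_alignment` (or a `pattern_alignment`).
#' @param cost a `cost_model` or selector (`"uniform"`, `"titv"`,
#'   `"protein_nt"`, or a step-matrix file path).
#' @param B number of bootstrap replicates (default 1000).
#' @param radius SPR radius (default 6).
#' @param ratchet_fraction fraction of sites the ratchet duplicates
#'   (default 0.5).
#' @param nni_fraction fraction of internal edges perturbed by NNI
#'   (default 0.5).
#' @param starts,keep candidate-set initialization parameters (100 / 5).
#' @param seed optional master seed; every stochastic draw (replicate
#'   weights, stepwise-addition orders and tie breaks, perturbation coin
#'   flips) flows from R's single RNG stream, so runs are reproducible.
#' @param use_abort use the lower-bound early abort when scoring replicates
#'   (results are identical with it off; it is purely a speed device).
#' @param consensus_threshold majority-rule threshold percentage.
#' @param verbose print search progress.
#' @return an object of class `mp_boot`: list with `best` (a
#'   `supported_tree`), `consensus`, `replicate_scores`, `replicate_trees`,
#'   `replicate_weights`, `state` (final `search_state`), `report` (named
#'   list of run facts).
#' @export
mp_bootstrap <- function(x, cost = "uniform", B = 1000L, radius = 6,
                         ratchet_fraction = 0.5, nni_fraction = 0.5,
                         starts = 100L, keep = 5L, seed = NULL,
                         use_abort = TRUE, consensus_threshold = 50,
                         verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pa <- if (inherits(x, "pattern_alignment")) x else compress_informative(x)
  cm <- resolve_cost(cost, pa$alphabet)
  bounds <- pattern_bounds(pa, cm)

  # step 1: bootstrap weight vectors
  reps <- make_replicates(pa, B)

  # initial step: candidate set + pattern evaluation order
  state <- init_candidate_set(pa, cm, radius = radius, starts = starts,
                              keep = keep)
  reps <- arm_replicates(reps, state$order, bounds)

  # steps 2-3: exploration, offering qualifying trees to all replicates
  env <- environment()
  hook <- function(tree, scores, total) {
    env$reps <- offer_tree(env$reps, tree, scores, use_abort = use_abort)
  }
  state <- exploration_loop(state, pa, cm, radius = radius, hook = hook,
                            nni_fraction = nni_fraction,
                            ratchet_fraction = ratchet_fraction,
                            verbose = verbose)

  # step 4: refinement
  reps <- refine(reps, pa, cm, radius = radius)

  # step 5: summary
  ibest <- which.min(state$C_totals)
  best <- state$C[[ibest]]
  supported <- support_on_best_tree(best, reps)
  cons <- majority_consensus(reps, best$tip_label,
                             threshold = consensus_threshold)

  report <- list(
    n_taxa = length(pa$taxa), m_informative = pa$m, k_patterns = pa$k,
    cost = if (cm$uniform) "uniform" else "non-uniform",
    B = reps$B, radius = radius,
    best_total = state$C_totals[ibest],
    iterations = state$iterations, n_prime = state$n_prime,
    stop_reason = sprintf("%d consecutive unsuccessful steps",
                          state$n_prime),
    mp_max = state$mp_max)

  structure(list(best = supported, consensus = cons,
                 replicate_scores = reps$best_score,
                 replicate_trees = reps$best_tree,
                 replicate_weights = reps$W,
                 state = state, pattern_alignment = pa, cost_model = cm,
                 report = report),
            class = "mp_boot")
}

#' @export
print.mp_boot <- function(x, ...) {
  r <- x$report
  cat(sprintf("Parsimony bootstrap: %d taxa, %d informative sites (%d patterns), %s cost\n",
              r$n_taxa, r$m_informative, r$k_patterns, r$cost))
  cat(sprintf("best MP score %s after %d exploration steps (n' = %d)\n",
              format(r$best_total), r$iterations, r$n_prime))
  cat(sprintf("%d bootstrap replicates; mean replicate score %.1f\n",
              r$B, mean(x$replicate_scores)))
  cat("best tree with supports:\n  ")
  cat(write_newick(x$best$tree, support = x$best$support), "\n")
  invisible(x)
}

#' Write the result files of a bootstrap run
#'
#' Writes `<prefix>.treefile` (best tree with integer supports),
#' `<prefix>.contree` (majority-rule consensus), `<prefix>.scores.tsv`
#' (per-replicate best scores) and `<prefix>.report.txt`.
#'
#' @param x an `mp_boot` object.
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_mp_boot <- function(x, prefix) {
  paths <- paste0(prefix, c(".treefile", ".contree", ".scores.tsv",
                            ".report.txt"))
  writeLines(write_newick(x$best$tree, support = x$best$support), paths[1L])
  ape::write.tree(x$consensus$tree, file = paths[2L])
  utils::write.table(
    data.frame(replicate = seq_along(x$replicate_scores),
               score = x$replicate_scores),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  r <- x$report
  writeLines(c(
    sprintf("taxa\t%d", r$n_taxa),
    sprintf("informative_sites\t%d", r$m_informative),
    sprintf("patterns\t%d", r$k_patterns),
    sprintf("cost\t%s", r$cost),
    sprintf("replicates\t%d", r$B),
    sprintf("spr_radius\t%s", format(r$radius)),
    sprintf("best_mp_score\t%s", format(r$best_total)),
    sprintf("exploration_steps\t%d", r$iterations),
    sprintf("stop_reason\t%s", r$stop_reason)), paths[4L])
  invisible(paths)
}

#' Command-line entry point
#'
#' `run_cli(c("--msa", "aln.fasta", "--format", "fasta", "--alphabet",
#' "dna", "--cost", "uniform", "-B", "1000", "--seed", "1", "--prefix",
#' "out"))` runs the full pipeline and writes the result files.  With
#' `--simulate n,sites,prob` it instead emits a synthetic fixture (FASTA
#' plus true-tree Newick) under the prefix.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the `mp_boot` object (or fixture paths).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("run_cli() needs the optparse package")
  spec <- list(
    optparse::make_option("--msa", type = "character"),
    optparse::make_option("--format", type = "character", default = "fasta"),
    optparse::make_option("--alphabet", type = "character", default = "dna"),
    optparse::make_option("--cost", type = "character", default = "uniform"),
    optparse::make_option(c("-B", "--replicates"), type = "integer",
                          default = 1000L),
    optparse::make_option("--radius", type = "integer", default = 6L),
    optparse::make_option("--ratchet", type = "double", default = 50),
    optparse::make_option("--nni", type = "double", default = 50),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--prefix", type = "character", default = "parsboot"),
    optparse::make_option("--simulate", type = "character", default = NULL))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (!is.null(opt$simulate)) {
    par <- as.numeric(strsplit(opt$simulate, ",")[[1L]])
    if (!is.null(opt$seed)) set.seed(opt$seed)
    sim <- evolve_alignment(n = par[1L], sites = par[2L],
                            subst_prob = par[3L], alphabet = opt$alphabet)
    write_fasta(sim$alignment, paste0(opt$prefix, ".fasta"))
    writeLines(write_newick(sim$tree), paste0(opt$prefix, ".truetree.nwk"))
    return(invisible(paste0(opt$prefix, c(".fasta", ".truetree.nwk"))))
  }
  aln <- read_alignment(opt$msa, format = opt$format,
                        alphabet = opt$alphabet)
  res <- mp_bootstrap(aln, cost = opt$cost, B = opt$replicates,
                      radius = opt$radius,
                      ratchet_fraction = opt$ratchet / 100,
                      nni_fraction = opt$nni / 100, seed = opt$seed,
                      verbose = TRUE)
  write_mp_boot(res, opt$prefix)
  print(res)
  invisible(res)
}
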