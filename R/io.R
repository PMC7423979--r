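# Readers/writers for the package's three external formats — multi-FASTA,
# newick, TSV — plus the pipeline driver binding all analysis stages.
# All site-indexed outputs are 1-based inclusive; TSV is the single
# tabular dialect.

#' Read a multi-FASTA file of DNA sequences
#'
#' Sequences are case-folded to uppercase and RNA `U` is converted to
#' `T`. Duplicate ids and non-IUPAC characters are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  # read as raw strings (no alphabet coercion), then validate strictly
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  iupac <- c(NUC, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
             "-", "?")
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), iupac)
    if (length(bad)) {
      stop("non-IUPAC character(s) '", paste(bad, collapse = ""),
           "' in sequence ", ids[i])
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a multi-FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a rooted tree from a newick file
#'
#' The tree must be rooted (no basal trifurcation); missing branch
#' lengths become 0 with a warning; internal nodes without labels are
#' auto-named `N1..Nk` in postorder.
#'
#' @param path Newick file.
#' @return A labelled `phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (inherits(tree, "multiPhylo")) {
    stop(path, " contains multiple trees; expected one rooted tree")
  }
  if (!ape::is.rooted(tree)) {
    stop("tree in ", path,
         " is unrooted (basal multifurcation); root it explicitly")
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  ensure_node_labels(tree)
}

#' Write a labelled tree to newick
#'
#' @param tree `phylo` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a branch-to-clade map from TSV
#'
#' Two columns: `branch` (child-node label) and `clade`.
#'
#' @param path TSV file with header.
#' @return Named character vector branch -> clade.
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("branch", "clade") %in% names(df)))
  stats::setNames(df$clade, df$branch)
}

#' Write a clade map to TSV
#' @param clade_map Named character vector branch -> clade.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(clade_map, path) {
  utils::write.table(
    data.frame(branch = names(clade_map), clade = unname(clade_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-condition FPKM table from TSV
#'
#' Requires a header with `gene`, `fpkm_gam`, `fpkm_spo`; further
#' condition columns (`ctrl`, `wl20`, ...) are kept as-is. Negative
#' FPKM values are rejected.
#'
#' @param path TSV file.
#' @return Data frame of class `expression_table`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fpkm_gam", "fpkm_spo")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("expression table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- vapply(df, is.numeric, logical(1))
  if (any(unlist(df[num]) < 0)) stop("negative FPKM values in ", path)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Per family: tip alignment FASTA (`famN.fasta`), true-ancestor FASTA
#' (`famN.ancestors.fasta`); plus the labelled tree (`tree.nwk`), the
#' clade map (`clades.tsv`) and the event-log truth TSV (`events.tsv`,
#' 1-based sites).
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in names(dataset$alignments)) {
    write_fasta(dataset$alignments[[f]], file.path(dir, paste0(f, ".fasta")))
    write_fasta(dataset$true_ancestors[[f]],
                file.path(dir, paste0(f, ".ancestors.fasta")))
  }
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_clade_map(dataset$config$clade_map, file.path(dir, "clades.tsv"))
  ev <- do.call(rbind, Map(function(f, log) {
    if (nrow(log)) cbind(family = f, log) else NULL
  }, names(dataset$event_log), dataset$event_log))
  if (is.null(ev)) {
    ev <- data.frame(family = character(0), branch = character(0),
                     site = integer(0), from = character(0),
                     to = character(0), time = numeric(0))
  }
  write_tsv(ev, file.path(dir, "events.tsv"))
  invisible(dir)
}

#' Run the full analysis pipeline on a set of families
#'
#' Executes model fitting, marginal ancestral reconstruction, directional
#' flux accounting, conservative/radical replacement rates and
#' composition statistics on codon alignments sharing one labelled tree
#' and clade partition; optionally classifies an expression table. All
#' outputs are written as TSV/FASTA under `out_dir` together with a JSON
#' manifest recording the configuration, seed and per-stage timings.
#'
#' @param alignments Named list of family alignments (named character
#'   vectors over the tree's tips), or a directory of `*.fasta` files.
#' @param tree Labelled rooted `phylo`, or a newick path.
#' @param clade_map Named character vector branch -> clade, or a TSV path.
#' @param compare Two clade names to contrast (default: the two most
#'   branch-rich clades).
#' @param expression Optional expression table (data frame or TSV path).
#' @param out_dir Output directory.
#' @param seed Seed for optimizer multi-starts.
#' @return List with the fitted model, reconstructions, flux table, rate
#'   comparison, enrichment/carbon reports and (optionally) the phase
#'   summary; also written under `out_dir`.
#' @export
run_pipeline <- function(alignments, tree, clade_map, compare = NULL,
                         expression = NULL, out_dir = "gcdrift_out",
                         seed = 1L) {
  t_all <- proc.time()[["elapsed"]]
  if (is.character(tree)) tree <- read_newick(tree)
  tree <- ensure_node_labels(tree)
  if (is.character(clade_map) && length(clade_map) == 1L &&
      file.exists(clade_map)) {
    clade_map <- read_clade_map(clade_map)
  }
  cmap <- validate_clade_map(tree, clade_map)
  if (is.character(alignments) && length(alignments) == 1L) {
    files <- list.files(alignments, pattern = "\\.fasta$",
                        full.names = TRUE)
    files <- files[!grepl("ancestors", files)]
    if (!length(files)) stop("no .fasta files in ", alignments)
    alignments <- lapply(files, read_fasta)
    names(alignments) <- sub("\\.fasta$", "", basename(files))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(compare)) {
    tb <- sort(table(cmap), decreasing = TRUE)
    if (length(tb) < 2) stop("need >= 2 clades to compare")
    compare <- names(tb)[1:2]
  }
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  fit <- stage("fit", fit_model(alignments, tree, cmap, seed = seed))
  recon <- stage("reconstruct", lapply(alignments, reconstruct_marginal,
                                       tree = tree, model = fit$model))
  node_seq_sets <- Map(function(aln, rec) c(aln, rec$node_sequences),
                       alignments, recon)
  flux <- stage("flux", clade_flux(node_seq_sets, tree, cmap,
                                   compare = compare))

  # branchwise rates: each clade's tips against the reconstructed root
  root_lab <- node_labels(tree)[root_node(tree)]
  tip_clade <- cmap[intersect(names(cmap), tree$tip.label)]
  rates <- stage("rates", {
    per_clade <- lapply(compare, function(cl) {
      tips <- names(tip_clade)[tip_clade == cl]
      do.call(rbind, Map(function(aln, rec) {
        pairwise_rates(aln[[tips[1]]], rec$node_sequences[[root_lab]])
      }, alignments, recon))
    })
    clade_comparison(per_clade[[1]], per_clade[[2]], labels = compare)
  })

  comp <- stage("composition", {
    fams_by_clade <- lapply(compare, function(cl) {
      tips <- names(tip_clade)[tip_clade == cl]
      lapply(alignments, function(aln) unname(aln[tips]))
    })
    list(enrichment = codon_enrichment(fams_by_clade[[1]],
                                       fams_by_clade[[2]]),
         carbon = carbon_usage_comparison(fams_by_clade[[1]],
                                          fams_by_clade[[2]]))
  })

  phases <- NULL
  if (!is.null(expression)) {
    if (is.character(expression)) {
      expression <- read_expression_table(expression)
    }
    phases <- stage("phases", {
      cls <- classify_phases(expression)
      list(table = cls, summary = phase_summary(cls))
    })
  }

  # outputs
  write_tsv(flux$branches, file.path(out_dir, "flux_branches.tsv"))
  write_tsv(flux$clades, file.path(out_dir, "flux_clades.tsv"))
  write_tsv(rates$per_clade, file.path(out_dir, "rates_clades.tsv"))
  write_tsv(comp$enrichment$table, file.path(out_dir, "codon_enrichment.tsv"))
  write_tsv(comp$carbon$per_aa, file.path(out_dir, "carbon_per_aa.tsv"))
  for (f in names(recon)) {
    write_fasta(recon[[f]]$node_sequences,
                file.path(out_dir, paste0(f, ".ancestors.fasta")))
  }
  if (!is.null(phases)) {
    write_tsv(phases$table, file.path(out_dir, "phase_labels.tsv"))
  }
  manifest <- list(
    package = "gcdrift",
    version = as.character(utils::packageVersion("gcdrift")),
    seed = seed,
    clades_compared = compare,
    n_families = length(alignments),
    stages = names(timings),
    timings_s = as.list(timings),
    model = list(kappa = fit$model$kappa,
                 theta = as.list(fit$model$theta),
                 theta_root = fit$model$theta_root),
    total_s = round(proc.time()[["elapsed"]] - t_all, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = fit, reconstructions = recon, flux = flux,
                 rates = rates, composition = comp, phases = phases,
                 manifest = manifest))
}
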