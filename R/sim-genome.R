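# Genome-evolution simulator: ancestral genome, whole-genome duplication,
# lineage divergence, rearrangements, scaffold fragmentation.
#
# A sim_genome is a list with
#   genes:  data.frame(gene_id, chrom, start, end, strand)  [0-based
#           half-open coordinates]
#   seqs:   named character vector of gene (transcript) sequences
# and carries a sim_truth alongside:
#   ancestry:  data.frame(gene_id, ancestor_id, event)
#   chrom_history: list(chrom -> list(ancestors = chr ids, events = chr))
#   chimeric_scaffolds, marker maps and planted expression truth are added
#   by the relevant generators.

GENE_GAP <- 200L  # intergenic spacer used when (re)laying out coordinates

new_truth <- function(genes) {
  list(ancestry = data.frame(gene_id = genes$gene_id,
                             ancestor_id = genes$gene_id,
                             event = "none",
                             stringsAsFactors = FALSE),
       chrom_history = setNames(
         lapply(unique(genes$chrom),
                function(ch) list(ancestors = ch, events = character(0))),
         unique(genes$chrom)))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# re-lay gene coordinates chromosome by chromosome, preserving order
relayout <- function(genes) {
  genes <- genes[order(genes$chrom, genes$start), ]
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    lens <- genes$end[idx] - genes$start[idx]
    starts <- cumsum(c(0L, head(lens + GENE_GAP, -1)))
    genes$start[idx] <- starts
    genes$end[idx] <- starts + lens
  }
  rownames(genes) <- NULL
  genes
}

#' Simulate an ancestral genome
#'
#' Places \code{genes_per_chromosome} non-overlapping genes (random
#' sequences) on each of \code{n_chromosomes_ancestral} chromosomes.
#' Coordinates are 0-based half-open. Output is fully determined by
#' \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @param chromosome_length optional fixed chromosome length in bp; an
#'   error is raised if the requested genes cannot fit.
#' @return list with \code{genome} (a \code{sim_genome}) and \code{truth}
#'   (a \code{sim_truth} ancestry record).
#' @export
simulate_ancestral_genome <- function(config, chromosome_length = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(chromosome_length) &&
      config$genes_per_chromosome *
        (max(config$gene_length_range) + GENE_GAP) > chromosome_length)
    stop("genes_per_chromosome x max gene length exceeds chromosome length")
  set.seed(config$seed)
  nchr <- config$n_chromosomes_ancestral
  gpc <- config$genes_per_chromosome
  chrom <- rep(sprintf("chr%02d", seq_len(nchr)), each = gpc)
  n <- nchr * gpc
  len_pool <- seq(config$gene_length_range[1],
                  config$gene_length_range[2])
  lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                      chrom = chrom, start = 0L, end = lens,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  genes <- relayout(genes)
  seqs <- setNames(vapply(genes$end - genes$start, random_seq,
                          character(1)), genes$gene_id)
  genome <- structure(list(genes = genes, seqs = seqs),
                      class = "sim_genome")
  list(genome = genome, truth = new_truth(genes))
}

# substitute exactly `count` distinct sites of `seq`, each to a different
# base; returns the mutated sequence
substitute_sites <- function(seq, sites) {
  if (length(sites) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in sites) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- sample(alt, 1)
  }
  paste(chars, collapse = "")
}

#' Apply a whole-genome duplication
#'
#' Doubles every chromosome and gene. Each duplicate pair is diverged by
#' substitutions at exactly \code{round(divergence_d * L)} distinct sites
#' (each to a different base), so the realized ungapped pair identity is
#' exactly \code{1 - round(dL)/L}. Divergence is shared between the two
#' copies: each chosen site is mutated in one copy at random, so both
#' copies drift away from the pre-duplication state, as after a real WGD.
#' Optionally a fraction of the new duplicate copies is lost again.
#'
#' @param genome,truth a \code{sim_genome} and its \code{sim_truth}.
#' @param divergence_d per-site divergence of each duplicate pair.
#' @param event label recorded in the ancestry table (e.g. \code{"3R"},
#'   \code{"4R"}, \code{"recent"}).
#' @param loss_fraction fraction of duplicate copies deleted after the
#'   duplication.
#' @return list with updated \code{genome} and \code{truth}.
#' @export
apply_wgd <- function(genome, truth, divergence_d, event = "wgd",
                      loss_fraction = 0) {
  stopifnot(inherits(genome, "sim_genome"), nrow(genome$genes) > 0,
            divergence_d >= 0, divergence_d <= 1)
  genes <- genome$genes
  dup <- genes
  dup$gene_id <- paste0(genes$gene_id, "d")
  dup$chrom <- paste0(genes$chrom, "D")
  new_seqs <- genome$seqs
  dup_seqs <- setNames(genome$seqs[genes$gene_id], dup$gene_id)
  for (k in seq_len(nrow(genes))) {
    L <- nchar(new_seqs[[genes$gene_id[k]]])
    nsub <- round(divergence_d * L)
    if (nsub == 0) next
    sites <- sample.int(L, nsub)
    to_a <- as.logical(rbinom(nsub, 1, 0.5))
    new_seqs[[genes$gene_id[k]]] <-
      substitute_sites(new_seqs[[genes$gene_id[k]]], sites[to_a])
    dup_seqs[[dup$gene_id[k]]] <-
      substitute_sites(dup_seqs[[dup$gene_id[k]]], sites[!to_a])
  }
  if (loss_fraction > 0) {
    n_lose <- round(loss_fraction * nrow(dup))
    if (n_lose > 0) {
      lost <- sample.int(nrow(dup), n_lose)
      dup <- dup[-lost, , drop = FALSE]
      dup_seqs <- dup_seqs[dup$gene_id]
    }
  }
  genome$genes <- relayout(rbind(genes, dup))
  genome$seqs <- c(new_seqs, dup_seqs)[genome$genes$gene_id]
  anc <- setNames(truth$ancestry$ancestor_id, truth$ancestry$gene_id)
  truth$ancestry <- rbind(
    truth$ancestry,
    data.frame(gene_id = dup$gene_id,
               ancestor_id = unname(anc[sub("d$", "", dup$gene_id)]),
               event = event, stringsAsFactors = FALSE))
  for (ch in unique(dup$chrom)) {
    src <- sub("D$", "", ch)
    truth$chrom_history[[ch]] <-
      list(ancestors = truth$chrom_history[[src]]$ancestors,
           events = c(truth$chrom_history[[src]]$events,
                      paste0("wgd:", event)))
  }
  list(genome = genome, truth = truth)
}

#' Diverge every gene of a genome (lineage/speciation divergence)
#'
#' Substitutes exactly \code{round(d * L)} distinct sites of every gene,
#' modelling the sequence divergence accumulated along one lineage since a
#' speciation event. Use on a copied genome to derive a comparator species
#' from a shared ancestor.
#'
#' @inheritParams apply_wgd
#' @param d per-site divergence applied to each gene.
#' @return list with updated \code{genome} and \code{truth} (the event is
#'   appended to every chromosome's history).
#' @export
diverge_genes <- function(genome, truth, d, event = "speciation") {
  stopifnot(inherits(genome, "sim_genome"), d >= 0, d <= 1)
  for (id in names(genome$seqs)) {
    L <- nchar(genome$seqs[[id]])
    nsub <- round(d * L)
    if (nsub > 0)
      genome$seqs[[id]] <- substitute_sites(genome$seqs[[id]],
                                            sample.int(L, nsub))
  }
  for (ch in names(truth$chrom_history))
    truth$chrom_history[[ch]]$events <-
      c(truth$chrom_history[[ch]]$events, paste0("diverge:", event))
  list(genome = genome, truth = truth)
}

#' Apply a chromosomal rearrangement
#'
#' Supported directives:
#' \describe{
#'   \item{fission}{\code{list(type = "fission", chrom =, after_gene = k)}:
#'     splits a chromosome between its k-th and (k+1)-th genes into two
#'     chromosomes (suffixes \code{p}/\code{q}).}
#'   \item{fusion}{\code{list(type = "fusion", chrom_a =, chrom_b =)}:
#'     joins two chromosomes end to end.}
#'   \item{translocation}{\code{list(type = "translocation", from =,
#'     genes = i:j, to =)}: moves the contiguous gene block \code{i:j}
#'     (in gene order) of \code{from} to the end of \code{to}.}
#' }
#' Breakpoints always fall between genes; gene content is conserved by
#' every directive (fission and fusion change the chromosome count by
#' +1/-1).
#'
#' @inheritParams apply_wgd
#' @param directive a directive list as described above.
#' @return list with updated \code{genome} and \code{truth}.
#' @export
apply_rearrangement <- function(genome, truth, directive) {
  stopifnot(inherits(genome, "sim_genome"), is.list(directive))
  genes <- genome$genes[order(genome$genes$chrom, genome$genes$start), ]
  type <- directive$type
  hist <- truth$chrom_history
  if (type == "fission") {
    ch <- directive$chrom
    idx <- which(genes$chrom == ch)
    if (length(idx) == 0) stop("unknown chromosome: ", ch)
    k <- directive$after_gene
    if (is.null(k) || k != round(k) || k < 1 || k >= length(idx))
      stop("fission breakpoint must fall between genes")
    newa <- paste0(ch, "p"); newb <- paste0(ch, "q")
    genes$chrom[idx[seq_len(k)]] <- newa
    genes$chrom[idx[-seq_len(k)]] <- newb
    hist[[newa]] <- list(ancestors = hist[[ch]]$ancestors,
                         events = c(hist[[ch]]$events, "fission"))
    hist[[newb]] <- hist[[newa]]
    hist[[ch]] <- NULL
  } else if (type == "fusion") {
    a <- directive$chrom_a; b <- directive$chrom_b
    if (!all(c(a, b) %in% genes$chrom)) stop("unknown chromosome in fusion")
    newc <- paste0(a, "+", b)
    ib <- which(genes$chrom == b)
    off <- max(genes$end[genes$chrom == a]) + GENE_GAP
    genes$start[ib] <- genes$start[ib] + off
    genes$end[ib] <- genes$end[ib] + off
    genes$chrom[genes$chrom %in% c(a, b)] <- newc
    hist[[newc]] <- list(
      ancestors = unique(c(hist[[a]]$ancestors, hist[[b]]$ancestors)),
      events = c(hist[[a]]$events, hist[[b]]$events, "fusion"))
    hist[[a]] <- NULL; hist[[b]] <- NULL
  } else if (type == "translocation") {
    from <- directive$from; to <- directive$to
    idx <- which(genes$chrom == from)
    if (length(idx) == 0 || !to %in% genes$chrom)
      stop("unknown chromosome in translocation")
    seg <- directive$genes
    if (any(seg < 1) || any(seg > length(idx)) ||
        !all(diff(sort(seg)) == 1))
      stop("translocated segment must be a contiguous gene block")
    moved <- idx[sort(seg)]
    off <- max(genes$end[genes$chrom == to]) + GENE_GAP -
      min(genes$start[moved])
    genes$chrom[moved] <- to
    genes$start[moved] <- genes$start[moved] + off
    genes$end[moved] <- genes$end[moved] + off
    hist[[to]] <- list(
      ancestors = unique(c(hist[[to]]$ancestors, hist[[from]]$ancestors)),
      events = c(hist[[to]]$events, "translocation_in"))
    hist[[from]]$events <- c(hist[[from]]$events, "translocation_out")
  } else stop("unknown rearrangement type: ", type)
  genome$genes <- relayout(genes)
  genome$seqs <- genome$seqs[genome$genes$gene_id]
  truth$chrom_history <- hist
  list(genome = genome, truth = truth)
}

#' Fragment chromosomes into scaffolds
#'
#' Cuts each chromosome at random inter-gene points so that the genome is
#' represented by \code{scaffold_n} scaffolds, and emits an anchor table
#' assigning each scaffold to the linkage group of its source chromosome
#' (with its order along the group). With \code{chimera_inject}, pairs of
#' scaffolds from different chromosomes are joined into single scaffolds
#' and flagged in the truth record; the final scaffold count is still
#' \code{scaffold_n}.
#'
#' @inheritParams apply_wgd
#' @param scaffold_n number of scaffolds (>= number of chromosomes).
#' @param chimera_inject logical.
#' @param n_chimeras number of chimeric joins when injecting.
#' @param cuts optional named list (chromosome -> integer vector of
#'   inter-gene cut points, "cut after gene k"); chromosomes listed here
#'   are cut exactly there, the remaining cut budget is placed randomly.
#' @return list with \code{scaffolds} (data.frame gene_id, scaffold,
#'   start, end, strand: transcript locations on scaffolds), \code{anchors}
#'   (data.frame scaffold, lg, lg_order), and updated \code{truth} with
#'   \code{chimeric_scaffolds}.
#' @export
fragment_into_scaffolds <- function(genome, truth, scaffold_n,
                                    chimera_inject = FALSE,
                                    n_chimeras = 2L, cuts = NULL,
                                    chimera_exclude_lg = character(0)) {
  genes <- genome$genes[order(genome$genes$chrom, genome$genes$start), ]
  chroms <- unique(genes$chrom)
  if (scaffold_n < length(chroms))
    stop("scaffold_n must be at least the chromosome count")
  fixed <- if (is.null(cuts)) list() else cuts
  if (!all(names(fixed) %in% chroms)) stop("cuts name unknown chromosome")
  n_target <- scaffold_n + (if (chimera_inject) n_chimeras else 0L)
  n_rand <- n_target - length(chroms) -
    sum(vapply(fixed, length, integer(1)))
  if (n_rand < 0) stop("cuts exceed scaffold_n budget")
  # distribute random cuts over remaining chromosomes
  free <- setdiff(chroms, names(fixed))
  avail <- vapply(free, function(ch) sum(genes$chrom == ch) - 1L,
                  integer(1))
  if (n_rand > sum(avail)) stop("scaffold_n too large for gene count")
  n_cut <- setNames(integer(length(free)), free)
  pool <- rep(free, avail)
  if (n_rand > 0) {
    take <- sample(pool, n_rand)
    tt <- table(take)
    n_cut[names(tt)] <- as.integer(tt)
  }
  genes$scaffold <- NA_character_
  scf_i <- 0L
  anchor <- list()
  for (ch in chroms) {
    idx <- which(genes$chrom == ch)
    breaks <- if (ch %in% names(fixed)) sort(as.integer(fixed[[ch]]))
              else if (n_cut[[ch]] > 0)
                sort(sample(seq_len(length(idx) - 1L), n_cut[[ch]]))
              else integer(0)
    if (any(breaks < 1 | breaks >= length(idx)))
      stop("cut point outside chromosome ", ch)
    bounds <- c(0L, breaks, length(idx))
    for (s in seq_len(length(bounds) - 1L)) {
      scf_i <- scf_i + 1L
      sid <- sprintf("scf%04d", scf_i)
      genes$scaffold[idx[(bounds[s] + 1L):bounds[s + 1L]]] <- sid
      anchor[[sid]] <- data.frame(scaffold = sid, lg = ch, lg_order = s,
                                  stringsAsFactors = FALSE)
    }
  }
  anchors <- do.call(rbind, anchor)
  rownames(anchors) <- NULL
  truth$chimeric_scaffolds <- character(0)
  if (chimera_inject && n_chimeras > 0) {
    for (j in seq_len(n_chimeras)) {
      sizes <- table(genes$scaffold)
      cand <- setdiff(names(sizes)[sizes >= 3], truth$chimeric_scaffolds)
      cand_lg <- setNames(anchors$lg, anchors$scaffold)[cand]
      cand <- cand[!cand_lg %in% chimera_exclude_lg]
      cand_lg <- cand_lg[cand]
      if (length(unique(cand_lg)) < 2) stop("not enough scaffolds to join")
      s1 <- sample(cand, 1)
      s2 <- sample(cand[cand_lg != cand_lg[[s1]]], 1)
      # graft s2's genes onto s1; s2 disappears, anchor keeps s1's LG slot
      genes$scaffold[genes$scaffold == s2] <- s1
      anchors <- anchors[anchors$scaffold != s2, , drop = FALSE]
      truth$chimeric_scaffolds <- c(truth$chimeric_scaffolds, s1)
    }
  }
  # scaffold-relative transcript coordinates, preserving gene order
  scf <- genes[, c("gene_id", "scaffold", "start", "end", "strand")]
  scf <- scf[order(scf$scaffold, scf$start), ]
  for (sid in unique(scf$scaffold)) {
    i <- which(scf$scaffold == sid)
    lens <- scf$end[i] - scf$start[i]
    st <- cumsum(c(0L, head(lens + GENE_GAP, -1)))
    scf$start[i] <- st
    scf$end[i] <- st + lens
  }
  rownames(scf) <- NULL
  # renumber lg_order densely after chimera removal
  anchors <- anchors[order(anchors$lg, anchors$lg_order), ]
  anchors$lg_order <- stats::ave(seq_len(nrow(anchors)), anchors$lg,
                                 FUN = seq_along)
  rownames(anchors) <- NULL
  list(scaffolds = scf, anchors = anchors, truth = truth)
}

#' Transcript location table of a simulated genome
#' @param genome a \code{sim_genome}.
#' @return data.frame with columns id, chrom_or_scaffold, start, end,
#'   strand (0-based half-open).
#' @export
transcript_locations <- function(genome) {
  data.frame(id = genome$genes$gene_id,
             chrom_or_scaffold = genome$genes$chrom,
             start = genome$genes$start, end = genome$genes$end,
             strand = genome$genes$strand, stringsAsFactors = FALSE)
}
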