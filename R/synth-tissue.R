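# Synthetic tissue generator with planted ground truth.
#
# The generator emulates the statistical structure the mapping and linking
# procedures assume: a 2D tissue with four spatially restricted cell types —
# two "wedge" compartments read out along a vertical-line landmark (a
# differentiation wavefront) and two concentric "ring" compartments read out
# radially — each carrying a latent axis position u in [0, 1]. Real RNA and
# ATAC cells draw u uniformly; gene expression follows smooth axis profiles
# (sigmoids or Gaussian bumps) of u plus Gaussian noise and Bernoulli
# dropout. Region accessibility is generated through an explicit topic model
# (one topic per cell type x axis segment, triangular segment weights), so
# the region-cell probabilities are exactly the product of the two
# column-stochastic factors. Planted positive-link regions track their
# gene's profile, negative-link regions mirror it (open where the gene is
# off), decoy regions carry independent noise, primed regions are
# ubiquitously accessible, and cell-type-specific "coupled" regions are
# accessible only around a bump in one type. Truth tables record every
# planted feature.

#' Specification of a synthetic tissue
#'
#' Defaults define the study conditions used throughout the package's tests:
#' 4 cell types, 500 cells per type in each modality, 40 genes each with one
#' planted link (half positive, half negative) and 10 decoy candidate
#' regions, expression noise sd 0.1, dropout 0.1, 20 axis segments (topics)
#' per cell type.
#'
#' @param n_cells_per_type Real cells per cell type and modality.
#' @param n_genes Number of genes (each with its own genomic locus).
#' @param n_pos_links,n_neg_links Planted positive/negative links (their sum
#'   must not exceed `n_genes`; remaining genes get only decoys).
#' @param n_decoys_per_gene Decoy candidate regions per gene.
#' @param n_specific,n_primed Cell-type-specific ("coupled") and ubiquitously
#'   accessible ("primed") enhancer regions.
#' @param noise_sd Gaussian noise sd on expression (accessibility noise is
#'   scaled from it).
#' @param dropout Bernoulli dropout probability on expression entries.
#' @param embedding_noise_sd Noise sd on the RNA embedding coordinates.
#' @param n_segments Axis segments (topics) per cell type.
#' @param seed Integer seed; identical specs and seeds give identical
#'   bundles.
#' @return A list of class `tissue_spec`.
#' @export
tissue_spec <- function(n_cells_per_type = 500, n_genes = 40,
                        n_pos_links = 20, n_neg_links = 20,
                        n_decoys_per_gene = 10, n_specific = 10, n_primed = 10,
                        noise_sd = 0.1, dropout = 0.1,
                        embedding_noise_sd = 0.25, n_segments = 20, seed = 1L) {
  if (n_pos_links + n_neg_links > n_genes)
    stopf("more planted links than genes")
  structure(as.list(environment()), class = "tissue_spec")
}

# Smooth axis profiles in [0, 1].
axis_profile <- function(kind, center, steep) {
  switch(kind,
         rise = function(u) 1 / (1 + exp(-steep * (u - center))),
         fall = function(u) 1 - 1 / (1 + exp(-steep * (u - center))),
         bump = function(u) exp(-(u - center)^2 / (2 * 0.15^2)),
         stopf("unknown profile kind '%s'", kind))
}

# The fixed 100x100 tissue drawing: two wedges + two rings.
build_tissue_template <- function() {
  grid <- matrix(0L, 100, 100) # rows = y, cols = x
  grid[1:25, 1:20] <- 1L
  grid[1:25, 21:40] <- 2L
  rows <- row(grid); cols <- col(grid)
  rad <- sqrt((cols - 70)^2 + (rows - 50)^2)
  grid[rad >= 5 & rad <= 10] <- 3L
  grid[rad >= 10.5 & rad <= 15] <- 4L
  template_from_label_grid(
    grid, c(`1` = "eyeA", `2` = "eyeB", `3` = "ringA", `4` = "ringB"),
    landmarks = list(
      landmark(c("eyeA", "eyeB"), "axis_x", x0 = 20.5, direction = "increasing"),
      landmark(c("ringA", "ringB"), "radial", x0 = 70, y0 = 50,
               direction = "increasing")
    ))
}

#' Generate a synthetic tissue bundle
#'
#' @param spec A [tissue_spec()].
#' @return A list of class `tissue_bundle` with components `template`,
#'   `regions`, `genes`, `rna` (cells, embedding, expression), `atac` (cells,
#'   embedding, topic model), `enhancers` (intervals, binary activity over
#'   virtual cells) and `truth` (latent positions, planted links, region and
#'   enhancer classes, per-type root cells).
#' @export
make_tissue <- function(spec = tissue_spec()) {
  stopifnot(inherits(spec, "tissue_spec"))
  withr::with_seed(spec$seed, {
    types <- c("eyeA", "eyeB", "ringA", "ringB")
    template <- build_tissue_template()
    dist <- landmark_distances(template)
    cells <- template$cells
    u_virtual <- stats::setNames(rep(NA_real_, nrow(cells)), cells$vcell_id)
    for (ty in types) {
      ids <- cells$vcell_id[cells$cell_type == ty]
      d <- dist[ids]
      u_virtual[ids] <- (d - min(d)) / (max(d) - min(d))
    }
    type_virtual <- stats::setNames(cells$cell_type, cells$vcell_id)

    ## gene catalogue: locus, strand, profile, home type, planted class
    n_genes <- spec$n_genes
    gene_ids <- sprintf("g%02d", seq_len(n_genes))
    home <- rep(types, length.out = n_genes)
    kind <- rep(c("rise", "fall", "bump"), length.out = n_genes)
    center <- stats::runif(n_genes, 0.3, 0.7)
    steep <- stats::runif(n_genes, 8, 12)
    tss0 <- 200000L * seq_len(n_genes)
    strand <- rep(c("+", "-"), length.out = n_genes)
    tss_list <- lapply(seq_len(n_genes), function(g) {
      if (g <= 2) c(tss0[g], tss0[g] + 300L) else tss0[g]
    })
    introns <- rep(list(matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("start", "end")))), n_genes)
    introns[[3]] <- matrix(c(tss0[3] + 60000L, tss0[3] + 70000L), 1, 2,
                           dimnames = list(NULL, c("start", "end")))
    genes <- gene_models(gene_ids, chrom = rep("chrL", n_genes), strand = strand,
                         tss_list = tss_list, introns = introns)
    link_class <- c(rep("pos", spec$n_pos_links), rep("neg", spec$n_neg_links),
                    rep("none", n_genes - spec$n_pos_links - spec$n_neg_links))

    ## regions: planted + decoys per gene on chrL; enhancer regions on chrE
    decoy_offsets <- c(-48000L, -38000L, -28000L, -18000L, -6000L,
                       4000L, 14000L, 24000L, 34000L, 44000L)
    region_rows <- list()
    for (g in seq_len(n_genes)) {
      if (link_class[g] != "none")
        region_rows[[length(region_rows) + 1L]] <-
          data.frame(chrom = "chrL", start = tss0[g] + 8000L,
                     end = tss0[g] + 8500L, id = sprintf("%s_p", gene_ids[g]),
                     class = link_class[g], gene_id = gene_ids[g])
      offs <- decoy_offsets[seq_len(spec$n_decoys_per_gene)]
      if (g == 3 && spec$n_decoys_per_gene >= 1) offs[length(offs)] <- 65000L # intronic decoy
      for (j in seq_along(offs))
        region_rows[[length(region_rows) + 1L]] <-
          data.frame(chrom = "chrL", start = tss0[g] + offs[j],
                     end = tss0[g] + offs[j] + 500L,
                     id = sprintf("%s_d%02d", gene_ids[g], j),
                     class = "decoy", gene_id = gene_ids[g])
    }
    spec_ids <- sprintf("spec%02d", seq_len(spec$n_specific))
    primed_ids <- sprintf("primed%02d", seq_len(spec$n_primed))
    enh_start <- 1000L + 5000L * seq_len(spec$n_specific + spec$n_primed)
    for (j in seq_len(spec$n_specific))
      region_rows[[length(region_rows) + 1L]] <-
        data.frame(chrom = "chrE", start = enh_start[j], end = enh_start[j] + 500L,
                   id = spec_ids[j], class = "specific", gene_id = NA_character_)
    for (j in seq_len(spec$n_primed))
      region_rows[[length(region_rows) + 1L]] <-
        data.frame(chrom = "chrE", start = enh_start[spec$n_specific + j],
                   end = enh_start[spec$n_specific + j] + 500L,
                   id = primed_ids[j], class = "primed", gene_id = NA_character_)
    region_rows[[length(region_rows) + 1L]] <-
      data.frame(chrom = "chrBG", start = 0L, end = 1000L, id = "rbg",
                 class = "background", gene_id = NA_character_)
    region_info <- do.call(rbind, region_rows)
    regions <- region_info[, c("chrom", "start", "end", "id")]
    rownames(regions) <- rownames(region_info) <- NULL

    ## per-region accessibility profile a_r(type, u)
    spec_home <- rep(types, length.out = spec$n_specific)
    spec_center <- stats::runif(spec$n_specific, 0.3, 0.7)
    prof_gene <- lapply(seq_len(n_genes), function(g)
      axis_profile(kind[g], center[g], steep[g]))
    names(prof_gene) <- gene_ids
    region_value <- function(rid, ty, u) {
      info <- region_info[region_info$id == rid, ]
      switch(info$class,
        pos = {
          g <- info$gene_id
          ifelse(ty == home[match(g, gene_ids)],
                 0.05 + 0.9 * prof_gene[[g]](u), 0.05)
        },
        neg = {
          g <- info$gene_id
          ifelse(ty == home[match(g, gene_ids)],
                 0.95 - 0.9 * prof_gene[[g]](u), 0.95)
        },
        specific = {
          j <- match(rid, spec_ids)
          ifelse(ty == spec_home[j],
                 0.02 + 0.95 * exp(-(u - spec_center[j])^2 / (2 * 0.15^2)), 0.02)
        },
        primed = rep(0.8, length(u)),
        background = rep(0, length(u)),
        stopf("decoys are filled directly")
      )
    }

    ## topic model: one topic per (type, segment)
    K <- spec$n_segments
    seg_u <- seq(0, 1, length.out = K) # linear B-spline knots: weights sum to 1 on [0,1]
    topic_ids <- as.vector(outer(seq_len(K), types,
                                 function(k, ty) sprintf("%s_t%02d", ty, k)))
    topic_type <- rep(types, each = K)
    topic_u <- rep(seg_u, times = length(types))
    n_topics <- length(topic_ids)

    region_topic <- matrix(0, nrow(regions), n_topics,
                           dimnames = list(regions$id, topic_ids))
    structured <- region_info$id[region_info$class != "decoy" &
                                   region_info$class != "background"]
    for (rid in structured)
      region_topic[rid, ] <- region_value(rid, topic_type, topic_u)
    decoys <- region_info$id[region_info$class == "decoy"]
    region_topic[decoys, ] <- stats::runif(length(decoys) * n_topics, 0.05, 0.35)
    jitter_sd <- spec$noise_sd * 0.05
    if (jitter_sd > 0) {
      jit <- matrix(stats::rnorm(length(region_topic), 0, jitter_sd),
                    nrow(region_topic))
      region_topic <- pmax(region_topic + jit, 1e-4)
      region_topic["rbg", ] <- 0
    }
    z <- colSums(region_topic)
    pad <- max(z) + 0.5 - z
    region_topic["rbg", ] <- pad
    region_topic <- region_topic / (max(z) + 0.5)

    ## real cells for both modalities
    make_cells <- function(prefix) {
      n <- spec$n_cells_per_type
      data.frame(
        cell_id = sprintf("%s_%s_%04d", prefix, rep(types, each = n),
                          rep(seq_len(n), times = length(types))),
        cell_type = rep(types, each = n),
        u = stats::runif(n * length(types))
      )
    }
    rna_cells <- make_cells("rna")
    atac_cells <- make_cells("atac")

    ## topic-cell distribution: triangular segment weights + small baseline
    topic_cell <- matrix(0.002, n_topics, nrow(atac_cells),
                         dimnames = list(topic_ids, atac_cells$cell_id))
    for (i in seq_len(nrow(atac_cells))) {
      own <- topic_type == atac_cells$cell_type[i]
      topic_cell[own, i] <- topic_cell[own, i] +
        pmax(0, 1 - abs(atac_cells$u[i] - seg_u) * (K - 1))
    }
    topic_cell <- sweep(topic_cell, 2, colSums(topic_cell), `/`)
    model <- topic_model(region_topic, topic_cell)

    ## expression: profile of u in the home type, baseline elsewhere
    expr_mean <- matrix(0.05, n_genes, nrow(rna_cells),
                        dimnames = list(gene_ids, rna_cells$cell_id))
    for (g in seq_len(n_genes)) {
      sel <- rna_cells$cell_type == home[g]
      expr_mean[g, sel] <- 0.1 + 0.9 * prof_gene[[g]](rna_cells$u[sel])
    }
    expr <- expr_mean
    if (spec$noise_sd > 0)
      expr <- expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd), nrow(expr))
    expr <- pmax(expr, 0)
    if (spec$dropout > 0) {
      if (spec$dropout >= 1) warnf("dropout >= 1: all expression entries zeroed")
      drop <- matrix(stats::runif(length(expr)) < spec$dropout, nrow(expr))
      expr[drop] <- 0
    }

    ## embeddings: RNA = noisy 1-D axis; ATAC = topic contributions
    rna_embedding <- matrix(stats::rnorm(nrow(rna_cells) * 5, 0,
                                         spec$embedding_noise_sd),
                            nrow(rna_cells), 5,
                            dimnames = list(rna_cells$cell_id, paste0("pc", 1:5)))
    rna_embedding[, 1] <- rna_embedding[, 1] + rna_cells$u * 10
    # topic contributions plus estimation noise (posterior contributions of a
    # fitted topic model are themselves noisy estimates)
    atac_embedding <- t(topic_cell) +
      matrix(stats::rnorm(length(topic_cell), 0, spec$embedding_noise_sd * 0.08),
             ncol(topic_cell), nrow(topic_cell))

    ## enhancer intervals + binary activity over virtual cells
    enh_rows <- list()
    for (j in seq_len(spec$n_specific))
      enh_rows[[length(enh_rows) + 1L]] <- data.frame(
        chrom = "chrE", start = enh_start[j] - 500L,
        end = enh_start[j] + 1000L, id = sprintf("enhS%02d", j))
    for (j in seq_len(spec$n_primed))
      enh_rows[[length(enh_rows) + 1L]] <- data.frame(
        chrom = "chrE", start = enh_start[spec$n_specific + j] - 500L,
        end = enh_start[spec$n_specific + j] + 1000L, id = sprintf("enhP%02d", j))
    enhancers <- do.call(rbind, enh_rows)
    enh_class <- c(rep("coupled", spec$n_specific), rep("primed", spec$n_primed))
    primed_home <- rep(types, length.out = spec$n_primed)
    activity <- matrix(0L, nrow(enhancers), nrow(cells),
                       dimnames = list(enhancers$id, cells$vcell_id))
    for (j in seq_len(spec$n_specific)) {
      on <- type_virtual == spec_home[j] &
        abs(u_virtual - spec_center[j]) < 0.15 * sqrt(2 * log(2))
      activity[sprintf("enhS%02d", j), on] <- 1L
    }
    for (j in seq_len(spec$n_primed)) {
      on <- type_virtual == primed_home[j] & u_virtual >= 0.35 & u_virtual <= 0.65
      activity[sprintf("enhP%02d", j), on] <- 1L
    }

    truth_links <- region_info[region_info$class %in% c("pos", "neg"),
                               c("gene_id", "id", "class")]
    names(truth_links) <- c("gene_id", "region_id", "class")
    truth_links$sign <- ifelse(truth_links$class == "pos", 1L, -1L)
    rownames(truth_links) <- NULL

    root_of <- function(cells_df) {
      vapply(types, function(ty) {
        sub <- cells_df[cells_df$cell_type == ty, ]
        sub$cell_id[which.min(sub$u)]
      }, character(1))
    }

    structure(list(
      spec = spec,
      template = template,
      regions = regions,
      genes = genes,
      rna = list(cells = rna_cells, embedding = rna_embedding, expression = expr),
      atac = list(cells = atac_cells, embedding = atac_embedding, model = model),
      enhancers = list(intervals = enhancers, activity = activity),
      truth = list(
        u_virtual = u_virtual, type_virtual = type_virtual,
        u_rna = stats::setNames(rna_cells$u, rna_cells$cell_id),
        u_atac = stats::setNames(atac_cells$u, atac_cells$cell_id),
        links = truth_links,
        region_class = region_info[, c("id", "class", "gene_id")],
        enhancer_class = data.frame(enhancer_id = enhancers$id, class = enh_class),
        roots_rna = root_of(rna_cells), roots_atac = root_of(atac_cells),
        gene_profiles = data.frame(gene_id = gene_ids, home_type = home,
                                   kind = kind, center = center, steep = steep)
      )
    ), class = "tissue_bundle")
  })
}

#' Write a tissue bundle to a directory in standard formats
#'
#' Emits the template and landmark TSVs, the cell tables, expression and
#' topic matrices (TSV), the region and enhancer BEDs, the gene-model TSV,
#' the binary activity matrix, and the truth tables.
#'
#' @param bundle A `tissue_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tissue <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_template(bundle$template, p("template.tsv"), p("landmarks.tsv"))
  write_bed(bundle$regions, p("regions.bed"))
  write_bed(bundle$enhancers$intervals, p("enhancers.bed"))
  write_gene_models(bundle$genes, p("genes.tsv"))
  utils::write.table(bundle$rna$cells, p("rna_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$atac$cells, p("atac_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(bundle$rna$expression, p("expression.tsv"))
  write_matrix(bundle$rna$embedding, p("rna_embedding.tsv"))
  write_matrix(bundle$atac$embedding, p("atac_embedding.tsv"))
  write_matrix(bundle$atac$model$region_topic, p("region_topic.tsv"))
  write_matrix(bundle$atac$model$topic_cell, p("topic_cell.tsv"))
  storage.mode(bundle$enhancers$activity) <- "double"
  write_matrix(bundle$enhancers$activity, p("activity.tsv"))
  utils::write.table(bundle$truth$links, p("truth_links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$region_class, p("truth_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
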