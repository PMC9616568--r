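# Synthetic skeleton populations and synapse tables with known ground truth.
#
# The generator emulates the geometry the pipeline is built for: homotypic
# bundles of 1-8 neurons threading three spatially separated neuropil regions
# joined by thin backbone tracts. Each homotype owns an anchor point inside
# every region; each member neuron adds a constant lateral offset (scale
# sigma, the intra-bundle spread) and arborises as a Gaussian node cloud
# around the anchor. Arborisation is a point cloud, not a realistic branched
# tree, because every downstream statistic is a point-cloud functional; a
# nearest-neighbour branching mode exists for SWC realism.

#' Bundle specification table
#'
#' Convenience constructor for the per-homotype generator parameters.
#'
#' @param homotype character vector of glomerulus labels.
#' @param n_neurons neurons per homotype (1-8 in the emulated datasets).
#' @param sigma intra-bundle lateral spread in micrometres.
#' @param nodes_per_region arbor nodes per neuron per region.
#' @return data frame usable as `specs` in [generate_population()].
#' @export
bundle_spec <- function(homotype, n_neurons, sigma, nodes_per_region = 30L) {
  data.frame(homotype = as.character(homotype),
             n_neurons = as.integer(n_neurons),
             sigma = as.numeric(sigma),
             nodes_per_region = as.integer(nodes_per_region),
             stringsAsFactors = FALSE)
}

runif_ball <- function(n, radius) {
  # uniform in a 3-ball by rejection
  out <- matrix(NA_real_, n, 3L)
  filled <- 0L
  while (filled < n) {
    cand <- matrix(stats::runif(3L * (n - filled) * 2L, -1, 1), ncol = 3L)
    keep <- rowSums(cand^2) <= 1
    take <- utils::head(which(keep), n - filled)
    if (length(take)) {
      out[(filled + 1L):(filled + length(take)), ] <- cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  out * radius
}

#' Generate a synthetic uPN population
#'
#' @param specs bundle table from [bundle_spec()] (columns `homotype`,
#'   `n_neurons`, `sigma`, optional `nodes_per_region`, `odor_type`,
#'   `valence`, `tract`).
#' @param seed RNG seed (required; output is byte-reproducible given it).
#' @param region_centers 3 x 3 matrix of region centres (rows AL, MB_calyx,
#'   LH), micrometres. Default: collinear along x at 0, 60, 120.
#' @param region_radii length-3 region radii (default 10 um each).
#' @param anchor_spread radius of the per-region homotype-anchor layout
#'   (default `region_radii`).
#' @param anchor_mode `"shell"` spaces homotype anchors evenly on a circle of
#'   radius `anchor_spread` (deterministic inter-homotype separation, the
#'   separable regime); `"random"` draws anchors uniformly in the ball.
#' @param arbor_sd Gaussian arbor spread around the anchor (default 1 um).
#' @param backbone add connector nodes along the inter-region tracts.
#' @param backbone_step spacing of backbone nodes in micrometres.
#' @param arbor_mode `"cloud"` (star topology) or `"tree"` (each node attaches
#'   to the nearest earlier node; same point distribution).
#' @param separable assert the separable regime: region gaps must exceed
#'   3 * (max sigma + arbor_sd); violating specs are an error.
#' @return list with `skeletons` (list of `skeleton`), `annotations`
#'   (`neuron_table`), `ground_truth` (data frame `neuron_id`, `node_id`,
#'   `region` with `"backbone"` for connector nodes), and `manifest`
#'   (parameters and seed).
#' @export
generate_population <- function(specs, seed,
                                region_centers = rbind(AL = c(0, 0, 0),
                                                       MB_calyx = c(60, 0, 0),
                                                       LH = c(120, 0, 0)),
                                region_radii = c(10, 10, 10),
                                anchor_spread = region_radii,
                                anchor_mode = c("shell", "random"),
                                arbor_sd = 1, backbone = TRUE,
                                backbone_step = 2,
                                arbor_mode = c("cloud", "tree"),
                                separable = TRUE) {
  anchor_mode <- match.arg(anchor_mode)
  arbor_mode <- match.arg(arbor_mode)
  assert_that(is_count(seed, min = 0L), "seed must be a non-negative integer")
  assert_that(is.data.frame(specs) &&
                all(c("homotype", "n_neurons", "sigma") %in% names(specs)),
              "specs must carry homotype, n_neurons and sigma columns")
  assert_that(!anyDuplicated(specs$homotype), "duplicate homotype in specs")
  assert_that(all(specs$n_neurons >= 1L), "n_neurons must be >= 1")
  assert_that(all(specs$sigma > 0), "sigma must be positive")
  centers <- as.matrix(region_centers)
  assert_that(nrow(centers) == 3L && ncol(centers) == 3L,
              "region_centers must be a 3 x 3 matrix")
  if (separable) {
    margin <- max(specs$sigma) * 3 + 3 * arbor_sd
    for (i in 1:2) for (j in (i + 1):3) {
      gap <- sqrt(sum((centers[i, ] - centers[j, ])^2)) -
        region_radii[i] - region_radii[j]
      if (gap <= margin) {
        stop_("impossible spec in the separable regime: region gap %.1f um <= spread margin %.1f um",
              gap, margin)
      }
    }
  }
  if (is.null(specs$nodes_per_region)) specs$nodes_per_region <- 30L
  set.seed(seed)

  nh <- nrow(specs)
  # per-region homotype anchors
  anchors <- vector("list", 3L)
  for (r in 1:3) {
    if (anchor_mode == "shell") {
      ang <- 2 * pi * (seq_len(nh) - 1L) / nh + stats::runif(1, 0, 2 * pi)
      lay <- cbind(0, cos(ang), sin(ang)) * anchor_spread[r]
    } else {
      lay <- runif_ball(nh, anchor_spread[r])
    }
    anchors[[r]] <- sweep(lay, 2L, centers[r, ], `+`)
  }

  valences <- homotype_valences()
  skeletons <- list()
  ann <- list()
  truth <- list()
  for (h in seq_len(nh)) {
    X <- specs$homotype[h]
    npr <- specs$nodes_per_region[h]
    for (i in seq_len(specs$n_neurons[h])) {
      nid <- sprintf("%s_%d", X, i)
      offset <- stats::rnorm(3L, 0, specs$sigma[h])
      pts <- list(); regs <- list(); parents <- list()
      node_counter <- 0L
      attach_prev <- NA_integer_
      for (r in 1:3) {
        center_r <- anchors[[r]][h, ] + offset
        if (backbone && r > 1L) {
          from <- anchors[[r - 1L]][h, ] + offset
          len <- sqrt(sum((center_r - from)^2))
          nseg <- max(1L, floor(len / backbone_step))
          tfrac <- seq_len(nseg - 1L) / nseg
          if (length(tfrac)) {
            seg <- outer(tfrac, center_r - from) + rep(from, each = length(tfrac))
            pts[[length(pts) + 1L]] <- seg
            regs[[length(regs) + 1L]] <- rep("backbone", nrow(seg))
            parents[[length(parents) + 1L]] <-
              c(attach_prev, node_counter + seq_len(nrow(seg) - 1L))
            node_counter <- node_counter + nrow(seg)
            attach_prev <- node_counter
          }
        }
        cloud <- matrix(stats::rnorm(npr * 3L, 0, arbor_sd), ncol = 3L)
        cloud <- sweep(cloud, 2L, center_r, `+`)
        if (arbor_mode == "cloud") {
          par <- c(if (is.na(attach_prev)) -1L else attach_prev,
                   rep.int(node_counter + 1L, npr - 1L))
        } else {
          par <- integer(npr)
          par[1L] <- if (is.na(attach_prev)) -1L else attach_prev
          if (npr > 1L) for (k in 2:npr) {
            prev <- cloud[seq_len(k - 1L), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2L, cloud[k, ], `-`)^2)
            par[k] <- node_counter + which.min(d2)
          }
        }
        pts[[length(pts) + 1L]] <- cloud
        regs[[length(regs) + 1L]] <- rep(rownames(centers)[r], npr)
        parents[[length(parents) + 1L]] <- par
        node_counter <- node_counter + npr
        attach_prev <- node_counter - npr + 1L  # arbor root of this region
      }
      coords <- do.call(rbind, pts)
      region <- unlist(regs)
      parent <- unlist(parents)
      # geometric truth for backbone nodes that dip into a region sphere
      for (r in 1:3) {
        inside <- region == "backbone" &
          rowSums(sweep(coords, 2L, centers[r, ], `-`)^2) <= region_radii[r]^2
        region[inside] <- rownames(centers)[r]
      }
      nodes <- data.frame(node_id = seq_len(nrow(coords)),
                          structure = ifelse(region == "backbone", 2L, 5L),
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          radius = 0.1, parent_id = as.integer(parent))
      skeletons[[nid]] <- skeleton(nid, nodes)
      truth[[nid]] <- data.frame(neuron_id = nid, node_id = nodes$node_id,
                                 region = region, stringsAsFactors = FALSE)
      val <- valences$valence[match(X, valences$homotype)]
      ann[[nid]] <- data.frame(
        neuron_id = nid, homotype = X,
        odor_type = specs$odor_type[h] %||% ODOR_TYPES[(h - 1L) %% length(ODOR_TYPES) + 1L],
        valence = specs$valence[h] %||% (if (is.na(val)) "unknown" else val),
        tract = specs$tract[h] %||% "mALT",
        stringsAsFactors = FALSE)
    }
  }
  annotations <- neuron_table(do.call(rbind, ann), alias_map = NULL)
  list(skeletons = skeletons,
       annotations = annotations,
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       manifest = list(seed = seed, n_homotypes = nh,
                       n_neurons = sum(specs$n_neurons),
                       region_centers = centers, region_radii = region_radii,
                       anchor_spread = anchor_spread, anchor_mode = anchor_mode,
                       arbor_sd = arbor_sd, backbone = backbone,
                       backbone_step = backbone_step, arbor_mode = arbor_mode,
                       specs = specs))
}

#' Connectivity specification table
#'
#' @param homotype character vector of homotype labels.
#' @param n_partners third-order partners per homotype (excluding block
#'   partners).
#' @param specific_fraction fraction of those partners wired exclusively to
#'   the homotype; `round(specific_fraction * n_partners)` is the planted
#'   homotype-specific count.
#' @return data frame usable as `spec` in [generate_synapses()].
#' @export
connectivity_spec <- function(homotype, n_partners, specific_fraction) {
  assert_that(all(specific_fraction >= 0 & specific_fraction <= 1),
              "specific_fraction must lie in [0, 1]")
  data.frame(homotype = as.character(homotype),
             n_partners = as.integer(n_partners),
             specific_fraction = as.numeric(specific_fraction),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic synapse table with planted specificity
#'
#' Homotype-level wiring is planted first: each homotype receives its
#' exclusive ("specific") partners, the remaining partner slots are filled by
#' shared partners each wired to at least two homotypes, and optional shared
#' blocks wire a clique of homotypes to a common set of partners (emulating
#' food-odor style co-integration). The wiring is then expanded to uPN level
#' (each member uPN joins each of its homotype's edges with probability
#' `member_p`, at least one member per edge) and weighted with shifted
#' geometric synapse counts (support >= 1, mean `weight_mean`).
#'
#' @param spec table from [connectivity_spec()].
#' @param seed RNG seed.
#' @param upn_map named character vector uPN id -> homotype, or a
#'   `neuron_table` (e.g. from [generate_population()]).
#' @param interface interface tag for the records (default `"PN-KC"`).
#' @param shared_blocks optional list of `list(homotypes = c(...),
#'   n_partners = K)` block structures.
#' @param weight_mean mean synapse count per connected pair.
#' @param member_p probability each member uPN joins a homotype edge.
#' @return list with `table` (synapse table), `truth` (list holding the
#'   planted `specificity` data frame, the homotype-level `wiring` binary
#'   matrix, and the parameters).
#' @export
generate_synapses <- function(spec, seed, upn_map, interface = "PN-KC",
                              shared_blocks = list(), weight_mean = 5,
                              member_p = 0.9) {
  assert_that(is_count(seed, min = 0L), "seed must be a non-negative integer")
  assert_that(is.data.frame(spec) &&
                all(c("homotype", "n_partners", "specific_fraction") %in% names(spec)),
              "spec must carry homotype, n_partners and specific_fraction")
  if (inherits(upn_map, "neuron_table")) {
    upn_map <- stats::setNames(upn_map$homotype, upn_map$neuron_id)
  }
  missing <- setdiff(spec$homotype, upn_map)
  assert_that(!length(missing), "no uPNs mapped for homotype(s): %s",
              paste(missing, collapse = ", "))
  assert_that(weight_mean >= 1, "weight_mean must be >= 1")
  set.seed(seed)
  nh <- nrow(spec)
  partner_count <- 0L
  new_partner <- function() {
    partner_count <<- partner_count + 1L
    sprintf("%s_%04d", sub("^PN-", "", interface), partner_count)
  }
  edges <- list()  # homotype -> partner
  add_edge <- function(X, partner) {
    edges[[length(edges) + 1L]] <<- data.frame(homotype = X, post_id = partner,
                                               stringsAsFactors = FALSE)
  }
  n_sp <- as.integer(round(spec$specific_fraction * spec$n_partners))
  for (h in seq_len(nh)) {
    for (k in seq_len(n_sp[h])) add_edge(spec$homotype[h], new_partner())
  }
  slots <- spec$n_partners - n_sp
  names(slots) <- spec$homotype
  shared_partners <- character(0)
  shared_members <- list()  # partner -> homotypes
  while (sum(slots > 0) >= 2L) {
    open <- names(slots)[slots > 0]
    k <- min(length(open), sample(2:3, 1L))
    # favour the homotypes with the most open slots; break ties randomly
    pick <- open[order(-slots[open], stats::runif(length(open)))][seq_len(k)]
    p <- new_partner()
    shared_partners <- c(shared_partners, p)
    shared_members[[p]] <- pick
    for (X in pick) add_edge(X, p)
    slots[pick] <- slots[pick] - 1L
  }
  if (any(slots > 0)) {
    X <- names(slots)[slots > 0]
    assert_that(length(shared_partners) >= max(slots),
                "cannot satisfy shared-partner slots for '%s': no shared pool available", X)
    avail <- shared_partners[!vapply(shared_members[shared_partners],
                                     function(m) X %in% m, logical(1))]
    assert_that(length(avail) >= slots[X],
                "cannot satisfy shared-partner slots for '%s'", X)
    for (p in avail[seq_len(slots[X])]) {
      shared_members[[p]] <- c(shared_members[[p]], X)
      add_edge(X, p)
    }
  }
  for (blk in shared_blocks) {
    assert_that(all(blk$homotypes %in% spec$homotype),
                "shared block references unknown homotype(s)")
    assert_that(length(blk$homotypes) >= 2L, "a shared block needs >= 2 homotypes")
    for (k in seq_len(blk$n_partners)) {
      p <- new_partner()
      for (X in blk$homotypes) add_edge(X, p)
    }
  }
  edges <- do.call(rbind, edges)

  # planted truth at homotype level
  wiring <- matrix(0L, nh, partner_count,
                   dimnames = list(sort(spec$homotype),
                                   sprintf("%s_%04d", sub("^PN-", "", interface),
                                           seq_len(partner_count))))
  wiring[cbind(match(edges$homotype, rownames(wiring)),
               match(edges$post_id, colnames(wiring)))] <- 1L
  truth_spec <- specificity(wiring)

  # expand to uPN level with geometric weights
  recs <- list()
  for (e in seq_len(nrow(edges))) {
    members <- names(upn_map)[upn_map == edges$homotype[e]]
    joined <- members[stats::runif(length(members)) < member_p]
    if (!length(joined)) joined <- sample(members, 1L)
    w <- stats::rgeom(length(joined), prob = 1 / weight_mean) + 1L
    recs[[e]] <- data.frame(pre_id = joined, post_id = edges$post_id[e],
                            interface = interface, weight = w,
                            stringsAsFactors = FALSE)
  }
  table <- synapse_table(do.call(rbind, recs))
  list(table = table,
       truth = list(specificity = truth_spec, wiring = wiring,
                    params = list(seed = seed, interface = interface,
                                  weight_mean = weight_mean,
                                  member_p = member_p, spec = spec,
                                  shared_blocks = shared_blocks)))
}

#' Write a generated population to disk
#'
#' One SWC file per neuron plus the annotation table, the ground-truth
#' sidecar, and a manifest recording all generation parameters and the seed.
#'
#' @param population result of [generate_population()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in population$skeletons) {
    write_swc(s, file.path(dir, paste0(s$neuron_id, ".swc")))
  }
  utils::write.csv(population$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(population$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- population$manifest
  manifest$region_centers <- paste(apply(manifest$region_centers, 1L, paste,
                                         collapse = " "), collapse = "; ")
  manifest$specs <- paste(utils::capture.output(utils::write.csv(
    manifest$specs, row.names = FALSE)), collapse = "\n")
  writeLines(paste(names(manifest),
                   vapply(manifest, function(v) paste(format(v), collapse = " "),
                          character(1)), sep = " = "),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
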