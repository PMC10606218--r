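# Seeded rocking-bundle generator: every input the pipeline needs, with
# ground truth. An idealized 11-helix bundle emulates the LeuT-fold
# alternating-access motion: a mobile helix subset (the "rocking bundle")
# rotates rigidly against a static "hash" scaffold between an outwardly
# open (OO) and an inwardly open (IO) anchor; interpolated intermediates
# with optional coordinate noise stand in for predicted conformer pools.
# Contact communities that exist in exactly one state are planted by
# construction and asserted before any model is emitted.

HELIX_RADIUS <- 2.3   # A, CA helix radius
HELIX_RISE <- 1.5     # A per residue
HELIX_TURN <- 100     # degrees per residue (3.6 residues/turn)

#' Configuration of the synthetic rocking-bundle ensemble
#'
#' Defaults are the stated benchmark world: 11 helices of 20 residues, a
#' rocking bundle of h1/h2/h6/h7 rotated 25 degrees about the bundle axis
#' (plus a 2 A axial translation) between anchors, an OO-only contact
#' community joining h1-h5 and h1-h8 and an IO-only community joining
#' h6-h10 and h6-h11.
#'
#' @param n_helices Number of helices (the planted-community layout is
#'   defined for 11).
#' @param helix_length Residues per helix.
#' @param mobile Names of mobile-bundle helices.
#' @param rotation_deg Rigid rotation between anchors, degrees.
#' @param translation_A Axial translation between anchors, Angstroms.
#' @param t_values Interpolation coordinates in `[0, 1]` for the emitted
#'   models (0 = OO anchor, 1 = IO anchor).
#' @param noise_sigma Gaussian coordinate noise s.d. in Angstroms.
#' @param seed Integer seed; fixed seed means bit-identical output.
#' @param oo_community,io_community Helix triples carrying the planted
#'   state-specific contacts.
#' @param contact_cutoff CA contact cutoff used to define planted ground
#'   truth contacts (match the PSN cutoff you will analyse with).
#' @return A list of class `EnsembleConfig`.
#' @export
ensemble_config <- function(n_helices = 11, helix_length = 20,
                            mobile = c("h1", "h2", "h6", "h7"),
                            rotation_deg = 25, translation_A = 2,
                            t_values = seq(0, 1, by = 0.1),
                            noise_sigma = 0, seed = 1,
                            oo_community = c("h1", "h5", "h8"),
                            io_community = c("h6", "h10", "h11"),
                            contact_cutoff = 5.0) {
  helices <- paste0("h", seq_len(n_helices))
  if (!all(mobile %in% helices)) stop("mobile subset not among helix names")
  if (any(t_values < 0 | t_values > 1)) stop("t_values must lie in [0, 1]")
  if (rotation_deg <= 0) stop("rotation_deg must be positive")
  structure(list(
    n_helices = n_helices, helix_length = helix_length, mobile = mobile,
    rotation_deg = rotation_deg, translation_A = translation_A,
    t_values = t_values, noise_sigma = noise_sigma, seed = as.integer(seed),
    oo_community = oo_community, io_community = io_community,
    contact_cutoff = contact_cutoff, helices = helices
  ), class = "EnsembleConfig")
}

# xy axis positions, phases and tilts of the default bundle layout.
# h1 (mobile) is flanked in the OO anchor by static h5/h8, placed opposite
# to h1's displacement direction so the rocking motion breaks those
# contacts; h10/h11 are placed around the IO-anchor position of mobile h6
# so the same motion creates the IO contacts. Flank helices lean toward
# their mobile partner by a small crossing angle so contacts form
# connected multi-residue patches (as packed helices do) instead of
# isolated residue pairs.
bundle_layout <- function(cfg) {
  deg <- pi / 180
  rot <- function(p, ang) {
    c(cos(ang) * p[1] - sin(ang) * p[2], sin(ang) * p[1] + cos(ang) * p[2])
  }
  polar <- function(r, ang_deg) r * c(cos(ang_deg * deg), sin(ang_deg * deg))
  theta <- cfg$rotation_deg * deg
  contact_d <- 8.5   # flank axis distance (contacts via the 10 deg lean)
  w <- 5.5           # half-separation of the two flanking helices
  lean <- 10         # flank crossing angle, degrees

  pos <- list()
  # mobile community maker h1 and its OO flanks h5, h8
  p1 <- polar(18, 100)
  v1 <- rot(p1, theta) - p1
  v1 <- v1 / sqrt(sum(v1^2))
  w1 <- c(-v1[2], v1[1])
  a <- sqrt(contact_d^2 - w^2)
  pos$h1 <- p1
  pos$h5 <- p1 - a * v1 + w * w1
  pos$h8 <- p1 - a * v1 - w * w1
  # mobile community maker h6 and its IO flanks h10, h11 (placed around
  # h6's *post-rotation* position)
  p6 <- polar(18, 280)
  p6b <- rot(p6, theta)
  v6 <- p6b - p6
  v6 <- v6 / sqrt(sum(v6^2))
  w6 <- c(-v6[2], v6[1])
  pos$h6 <- p6
  pos$h10 <- p6b + a * v6 + w * w6
  pos$h11 <- p6b + a * v6 - w * w6
  # remaining helices on an outer ring, clear of both anchor states
  # (verified by the generator's contact assertions)
  pos$h2 <- polar(27, 25)
  pos$h3 <- polar(24, 160)
  pos$h4 <- polar(24, 200)
  pos$h7 <- polar(24, 245)
  pos$h9 <- polar(28, 355)
  # phases of the flank helices tuned so each planted helix pair forms one
  # connected contact patch at the 5 A CA cutoff
  phases <- c(h1 = 0, h2 = 40, h3 = 80, h4 = 120, h5 = 90, h6 = 0,
              h7 = 200, h8 = 90, h9 = 280, h10 = 90, h11 = 90)
  unit <- function(v) v / sqrt(sum(v^2))
  tilts <- list(
    h5 = list(deg = lean, dir = unit(pos$h1 - pos$h5)),
    h8 = list(deg = lean, dir = unit(pos$h1 - pos$h8)),
    h10 = list(deg = lean, dir = unit(p6b - pos$h10)),
    h11 = list(deg = lean, dir = unit(p6b - pos$h11))
  )
  list(pos = pos[cfg$helices], phases = phases[cfg$helices], tilts = tilts)
}

# CA coordinates of one ideal helix. The axis passes through (xy, z = 0),
# optionally tilted by tilt_deg toward the xy direction tilt_dir.
helix_coords <- function(xy, phase_deg, n_res, tilt_deg = 0,
                         tilt_dir = c(1, 0)) {
  deg <- pi / 180
  i <- seq_len(n_res) - 1
  mid <- (n_res - 1) / 2
  along <- HELIX_RISE * (i - mid)
  ax <- c(sin(tilt_deg * deg) * tilt_dir, cos(tilt_deg * deg))
  e1 <- c(-tilt_dir[2], tilt_dir[1], 0)
  e2 <- c(ax[3] * tilt_dir[1], ax[3] * tilt_dir[2], -sin(tilt_deg * deg))
  ang <- (phase_deg + HELIX_TURN * i) * deg
  ctr <- c(xy, 0)
  xyz <- t(vapply(seq_along(i), function(k) {
    ctr + ax * along[k] + HELIX_RADIUS * (e1 * cos(ang[k]) + e2 * sin(ang[k]))
  }, numeric(3)))
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# Full-bundle anchor coordinates. state = "A" (OO) or "B" (IO).
anchor_coords <- function(cfg, layout, state = c("A", "B")) {
  state <- match.arg(state)
  deg <- pi / 180
  theta <- cfg$rotation_deg * deg
  out <- NULL
  for (h in cfg$helices) {
    tl <- layout$tilts[[h]]
    xyz <- helix_coords(layout$pos[[h]], layout$phases[[h]],
                        cfg$helix_length,
                        tilt_deg = if (is.null(tl)) 0 else tl$deg,
                        tilt_dir = if (is.null(tl)) c(1, 0) else tl$dir)
    if (state == "B" && h %in% cfg$mobile) {
      rotm <- matrix(c(cos(theta), -sin(theta), 0,
                       sin(theta), cos(theta), 0,
                       0, 0, 1), 3, 3)
      xyz <- xyz %*% rotm
      xyz[, 3] <- xyz[, 3] + cfg$translation_A
      colnames(xyz) <- c("x", "y", "z")
    }
    out <- rbind(out, xyz)
  }
  out
}

# Inter-helix CA contact pairs (resno i < j, different helices) within
# cutoff, as a two-column matrix.
interhelix_contacts <- function(xyz, helix_id, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  hit <- hit[helix_id[hit[, 1]] != helix_id[hit[, 2]], , drop = FALSE]
  cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")

#' Generate a rocking-bundle conformer ensemble with ground truth
#'
#' Emits noiseless OO/IO anchor models plus one model per `t_values` entry
#' (linear Cartesian interpolation between anchors plus Gaussian coordinate
#' noise). Ground truth includes per-model state labels (t < 0.33 OO,
#' t > 0.67 IO, else intermediate), the planted state-specific contact
#' edges and their node communities, a segment table and the signature
#' segment groups a full conformation switch must move.
#'
#' The generator asserts before returning that the planted OO (IO)
#' contacts exist in exactly the OO (IO) anchor and that no other
#' inter-helix contacts exist in either anchor.
#'
#' @param cfg An [ensemble_config()].
#' @return List with `models` (named list of `StructureModel`s; the first
#'   two are the noiseless anchors `OO_anchor`, `IO_anchor`), `truth`
#'   (data.frame `model_id`, `t`, `state`), `template_sequence`,
#'   `segments`, `signature`, `planted` (OO/IO edge tables and node
#'   partitions), `anchors`, and the `cfg` used.
#' @export
generate_ensemble <- function(cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "EnsembleConfig"))
  layout <- bundle_layout(cfg)
  n <- cfg$n_helices * cfg$helix_length
  helix_id <- rep(cfg$helices, each = cfg$helix_length)
  xyz_a <- anchor_coords(cfg, layout, "A")
  xyz_b <- anchor_coords(cfg, layout, "B")

  ca <- interhelix_contacts(xyz_a, helix_id, cfg$contact_cutoff)
  cb <- interhelix_contacts(xyz_b, helix_id, cfg$contact_cutoff)
  oo_edges <- ca[!edge_key(ca) %in% edge_key(cb), , drop = FALSE]
  io_edges <- cb[!edge_key(cb) %in% edge_key(ca), , drop = FALSE]
  shared <- ca[edge_key(ca) %in% edge_key(cb), , drop = FALSE]
  seg_of_edges <- function(e) sort(unique(helix_id[as.vector(e)]))
  if (nrow(shared) > 0L)
    stop("geometry violation: state-shared inter-helix contacts present")
  if (!identical(seg_of_edges(oo_edges), sort(cfg$oo_community)))
    stop("geometry violation: OO contacts touch ",
         paste(seg_of_edges(oo_edges), collapse = ","))
  if (!identical(seg_of_edges(io_edges), sort(cfg$io_community)))
    stop("geometry violation: IO contacts touch ",
         paste(seg_of_edges(io_edges), collapse = ","))

  set.seed(cfg$seed)
  template_sequence <- paste(sample(AA_LETTERS, n, replace = TRUE),
                             collapse = "")
  aa <- strsplit(template_sequence, "")[[1]]

  segments <- segment_table(
    cfg$helices,
    start = (seq_len(cfg$n_helices) - 1) * cfg$helix_length + 1,
    end = seq_len(cfg$n_helices) * cfg$helix_length,
    class = "helix"
  )

  models <- list(
    OO_anchor = structure_model("OO_anchor", seq_len(n), aa, xyz_a,
                                source_tag = "synthetic"),
    IO_anchor = structure_model("IO_anchor", seq_len(n), aa, xyz_b,
                                source_tag = "synthetic")
  )
  truth <- data.frame(model_id = c("OO_anchor", "IO_anchor"),
                      t = c(0, 1), state = c("OO", "IO"),
                      stringsAsFactors = FALSE)
  id_count <- new.env()
  for (t in cfg$t_values) {
    id <- sprintf("model_t%.2f", t)
    # duplicate t values (e.g. noisy replicates) get distinct ids
    if (!is.null(id_count[[id]])) {
      id_count[[id]] <- id_count[[id]] + 1L
      id <- sprintf("%s_r%d", id, id_count[[id]])
    } else {
      id_count[[id]] <- 1L
    }
    xyz <- (1 - t) * xyz_a + t * xyz_b
    if (cfg$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * n, sd = cfg$noise_sigma), n, 3)
    models[[id]] <- structure_model(id, seq_len(n), aa, xyz,
                                    source_tag = "synthetic")
    truth <- rbind(truth, data.frame(
      model_id = id, t = t,
      state = if (t < 0.33) "OO" else if (t > 0.67) "IO" else "intermediate",
      stringsAsFactors = FALSE))
  }

  # node partition of a planted edge set: connected components, keeping
  # only communities of >= 3 members (the community-size convention used
  # by detect_communities)
  partition_of <- function(edges) {
    if (nrow(edges) == 0L) return(integer(0))
    g <- igraph::graph_from_edgelist(cbind(as.character(edges[, 1]),
                                           as.character(edges[, 2])),
                                     directed = FALSE)
    comp <- igraph::components(g)
    memb <- stats::setNames(as.integer(comp$membership), igraph::V(g)$name)
    memb[comp$csize[memb] >= 3]
  }

  list(
    models = models,
    truth = truth,
    template_sequence = template_sequence,
    segments = segments,
    signature = list(h1 = "h1", h2 = "h2", h6 = "h6", h7 = "h7",
                     gate = c("h10", "h11")),
    planted = list(
      oo_edges = as.data.frame(oo_edges),
      io_edges = as.data.frame(io_edges),
      oo_partition = partition_of(oo_edges),
      io_partition = partition_of(io_edges)
    ),
    anchors = c(oo = "OO_anchor", io = "IO_anchor"),
    layout = layout,
    cfg = cfg
  )
}

#' Mutation-response table for the synthetic predictor stand-in
#'
#' Maps mutation labels to target interpolation coordinates (and optional
#' per-helix extra radial displacements), with label-combination entries
#' that override singles -- this is what plants cooperative, antagonistic
#' and suppressor behaviour.
#'
#' @param singles Named list: label -> list(t = number in `[0, 1]`,
#'   helix_shift = named numeric vector of extra radial displacement in A,
#'   optional).
#' @param combos Named list keyed by sorted labels joined with `"+"` ->
#'   same structure as singles entries.
#' @param native_t Interpolation coordinate of the native (wild-type)
#'   model, default 1 (an IO template, mirroring the backward-switch
#'   design).
#' @return A list of class `ResponseTable`.
#' @export
response_table <- function(singles = list(), combos = list(), native_t = 1) {
  norm_entry <- function(e) {
    if (is.numeric(e)) e <- list(t = e)
    if (is.null(e$t)) e$t <- native_t
    if (e$t < 0 || e$t > 1) stop("t_target must lie in [0, 1]")
    if (is.null(e$helix_shift)) e$helix_shift <- numeric(0)
    e
  }
  structure(list(singles = lapply(singles, norm_entry),
                 combos = lapply(combos, norm_entry),
                 native_t = native_t),
            class = "ResponseTable")
}

combo_key <- function(labels) paste(sort(labels), collapse = "+")

# Resolve a label set against the table: combo entries take precedence;
# otherwise the single with the largest displacement from native wins;
# unlisted labels are conformation-silent (native t).
resolve_response <- function(labels, table) {
  stopifnot(inherits(table, "ResponseTable"))
  key <- combo_key(labels)
  if (key %in% names(table$combos)) return(table$combos[[key]])
  entries <- table$singles[intersect(labels, names(table$singles))]
  if (!length(entries))
    return(list(t = table$native_t, helix_shift = numeric(0)))
  shift <- do.call(c, unname(lapply(entries, function(e) e$helix_shift)))
  if (is.null(shift)) shift <- numeric(0)
  dt <- vapply(entries, function(e) abs(e$t - table$native_t), numeric(1))
  t <- entries[[which.max(dt)]]$t
  list(t = t, helix_shift = shift)
}

#' Simulate the predicted structure of a mutant (predictor stand-in)
#'
#' Stands in for an AF2/ColabFold run on a mutant sequence: returns the
#' ensemble geometry at the response table's target coordinate for the
#' mutation label set, with optional per-helix radial displacements and
#' coordinate noise. Labels absent from the table leave the conformation at
#' the native coordinate (conformation-silent).
#'
#' @param ensemble A [generate_ensemble()] result.
#' @param labels Character vector of mutation labels (a combination is
#'   looked up as a set).
#' @param table A [response_table()].
#' @param sigma Coordinate noise s.d. in A.
#' @param seed Integer seed.
#' @param mutant_sequence Optional mutated sequence (defaults to the
#'   template sequence).
#' @return A `StructureModel` named after the label set.
#' @export
simulate_mutant_response <- function(ensemble, labels, table,
                                     sigma = 0, seed = 1,
                                     mutant_sequence = NULL) {
  cfg <- ensemble$cfg
  resp <- resolve_response(labels, table)
  layout <- ensemble$layout
  xyz_a <- anchor_coords(cfg, layout, "A")
  xyz_b <- anchor_coords(cfg, layout, "B")
  xyz <- (1 - resp$t) * xyz_a + resp$t * xyz_b
  helix_id <- rep(cfg$helices, each = cfg$helix_length)
  for (h in names(resp$helix_shift)) {
    idx <- which(helix_id == h)
    ax <- layout$pos[[h]]
    dir <- ax / sqrt(sum(ax^2))
    xyz[idx, 1] <- xyz[idx, 1] + resp$helix_shift[[h]] * dir[1]
    xyz[idx, 2] <- xyz[idx, 2] + resp$helix_shift[[h]] * dir[2]
  }
  n <- nrow(xyz)
  if (sigma > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  }
  aa <- strsplit(if (is.null(mutant_sequence)) ensemble$template_sequence
                 else mutant_sequence, "")[[1]]
  structure_model(combo_key(labels), seq_len(n), aa, xyz,
                  source_tag = "synthetic")
}

#' Grouped multiple sequence alignment container
#'
#' @param seqs Character vector of equal-length (gapped) sequences.
#' @param groups Vector of group labels, one per sequence.
#' @return A list of class `GroupedMsa`.
#' @export
grouped_msa <- function(seqs, groups) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("all alignment rows must have equal length")
  if (length(groups) != length(seqs))
    stop("one group label per sequence required")
  structure(list(seqs = as.character(seqs),
                 groups = as.character(groups),
                 length = nchar(seqs[1])),
            class = "GroupedMsa")
}

#' @export
print.GroupedMsa <- function(x, ...) {
  cat("GroupedMsa: ", length(x$seqs), " sequences x ", x$length,
      " columns; groups: ",
      paste(sprintf("%s(%d)", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

#' Generate a group-structured alignment with planted signals
#'
#' Background columns share one residue profile across all groups (drawn
#' from a symmetric Dirichlet over the 20 amino acids). Type-ii columns fix
#' residue X in group 1 and Y != X in group 2 (group 3 and beyond follow
#' group 1); group-selective columns give one group (cycled) a private
#' conserved residue while the other groups share a different one.
#' Conservation is enforced as an exact count: `round(n_per_group *
#' conservation)` rows carry the consensus, the remainder are random
#' non-consensus residues.
#'
#' @param n_groups,n_per_group,n_columns Alignment dimensions (defaults 3
#'   groups of 11 sequences, 400 columns, mirroring a three-clade design).
#' @param planted_type_ii,planted_selective Disjoint column index vectors.
#' @param dirichlet_concentration Symmetric Dirichlet parameter for
#'   background column profiles (default 0.1: strongly conserved columns,
#'   as in within-family alignments of homologs).
#' @param conservation Consensus fraction at planted columns (default
#'   0.95).
#' @param seed Integer seed.
#' @return List with `msa` (a [grouped_msa()]) and `truth` (planted column
#'   tables).
#' @export
generate_grouped_msa <- function(n_groups = 3, n_per_group = 11,
                                 n_columns = 400,
                                 planted_type_ii = integer(0),
                                 planted_selective = integer(0),
                                 dirichlet_concentration = 0.1,
                                 conservation = 0.95, seed = 1) {
  if (length(intersect(planted_type_ii, planted_selective)))
    stop("planted column sets must be disjoint")
  if (any(c(planted_type_ii, planted_selective) > n_columns) ||
      any(c(planted_type_ii, planted_selective) < 1))
    stop("planted column index out of range")
  set.seed(seed)
  n <- n_groups * n_per_group
  group <- rep(paste0("g", seq_len(n_groups)), each = n_per_group)
  m <- matrix("", n, n_columns)
  n_cons <- round(n_per_group * conservation)

  fill_conserved <- function(consensus) {
    col <- rep(consensus, n_per_group)
    if (n_cons < n_per_group) {
      idx <- sample(n_per_group, n_per_group - n_cons)
      col[idx] <- sample(setdiff(AA_LETTERS, consensus),
                         length(idx), replace = TRUE)
    }
    col
  }

  sel_group <- stats::setNames(
    rep(paste0("g", seq_len(n_groups)), length.out = length(planted_selective)),
    planted_selective)

  for (j in seq_len(n_columns)) {
    if (j %in% planted_type_ii) {
      xy <- sample(AA_LETTERS, 2)
      for (g in seq_len(n_groups)) {
        consensus <- if (g == 2) xy[2] else xy[1]
        m[group == paste0("g", g), j] <- fill_conserved(consensus)
      }
    } else if (j %in% planted_selective) {
      xy <- sample(AA_LETTERS, 2)
      priv <- sel_group[[as.character(j)]]
      for (g in paste0("g", seq_len(n_groups))) {
        consensus <- if (g == priv) xy[2] else xy[1]
        m[group == g, j] <- fill_conserved(consensus)
      }
    } else {
      prof <- stats::rgamma(20, shape = dirichlet_concentration)
      prof <- prof / sum(prof)
      m[, j] <- sample(AA_LETTERS, n, replace = TRUE, prob = prof)
    }
  }
  msa <- grouped_msa(apply(m, 1, paste, collapse = ""), group)
  list(msa = msa,
       truth = list(
         type_ii = sort(planted_type_ii),
         selective = data.frame(
           column = as.integer(names(sel_group)),
           group = unname(sel_group))[order(as.integer(names(sel_group))), ,
                                      drop = FALSE]))
}
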