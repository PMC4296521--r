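# Seeded generators for barcode populations and morphometric cohorts with
# the statistical structure the analysis assumes: two species groups fixed
# at a planted set of diagnostic positions (~3% of the frame apart), low
# within-species variation spread over a configured number of haplotypes
# 1-3 substitutions apart with a dominant modal haplotype, optional
# degradation to 443-bp partials and 64-bp ID tags, and two separated
# morphometric distributions with optional intermediate hybrids.
#
# Generators are deterministic given (parameters, seed) and return truth
# tables sufficient to score every downstream stage.

# Frame region reserved for the ID-tag assay (primer sites + insert of
# swtl-ID1F/swtl-ID1R on the packaged frame): within-species variation is
# never placed here, nor at planted positions, so planted diagnostics stay
# strictly fixed and exact-match ID-tag amplification always succeeds.
ID_TAG_ASSAY_REGION <- 26:145

#' Specify one species for barcode simulation
#'
#' @param name species/group name (becomes the taxon label).
#' @param base_sequence the species' modal full-length barcode; it must
#'   already carry this species' states at the planted positions.
#' @param planted_sites data frame (position, state): this species' fixed
#'   states at the diagnostic positions planted between the pair.
#' @param n_haplotypes number of haplotypes to realize (default 10).
#' @param n_specimens specimens to draw (default 100).
#' @param haplotype_weights relative haplotype frequencies; default is a
#'   dominant modal haplotype weighted 67 with the remainder spread
#'   geometrically (mirroring a 67-of-94 modal haplotype census).
#' @param within_cap maximum tolerated within-species pairwise distance as
#'   a fraction (default 0.005).
#' @param id_prefix prefix for specimen ids.
#' @return a \code{species_model} list.
#' @export
species_model <- function(name, base_sequence, planted_sites,
                          n_haplotypes = 10L, n_specimens = 100L,
                          haplotype_weights = NULL, within_cap = 0.005,
                          id_prefix = toupper(substr(name, 1L, 3L))) {
  chars <- seq_chars(base_sequence)
  if (any(!chars %in% UNAMBIG)) {
    stop("base sequence must be unambiguous ACGT")
  }
  if (any(planted_sites$position < 1L |
          planted_sites$position > length(chars))) {
    stop("planted positions outside the frame")
  }
  if (any(chars[planted_sites$position] != planted_sites$state)) {
    stop("base sequence disagrees with planted states")
  }
  if (is.null(haplotype_weights)) {
    haplotype_weights <- if (n_haplotypes == 1L) 1 else
      c(67, 27 * 0.65^(seq_len(n_haplotypes - 1L) - 1L) /
          sum(0.65^(seq_len(n_haplotypes - 1L) - 1L)))
  }
  if (length(haplotype_weights) != n_haplotypes) {
    stop("haplotype_weights length must equal n_haplotypes")
  }
  structure(list(name = name, base_sequence = paste(chars, collapse = ""),
                 planted_sites = planted_sites,
                 n_haplotypes = as.integer(n_haplotypes),
                 n_specimens = as.integer(n_specimens),
                 haplotype_weights = haplotype_weights,
                 within_cap = within_cap, id_prefix = id_prefix),
            class = "species_model")
}

#' Default species pair mirroring the study conditions
#'
#' Species A uses the packaged holotype barcode as its modal haplotype and
#' the packaged 17-position table as planted diagnostics; species B is the
#' holotype with the 17 alternative states substituted. Ten haplotypes and
#' 100 specimens per species.
#'
#' @param n_specimens specimens per species.
#' @param n_haplotypes haplotypes per species.
#' @return list(model_a, model_b, sites) where sites is the planted
#'   diagnostic table (position, state_a, state_b).
#' @export
default_species_pair <- function(n_specimens = 100L, n_haplotypes = 10L) {
  frame <- holotype_frame()
  sites <- published_sites()
  base_a <- frame$reference_sequence
  chars_b <- seq_chars(base_a)
  chars_b[sites$position] <- sites$state_b
  model_a <- species_model("rumiko", base_a,
                           data.frame(position = sites$position,
                                      state = sites$state_a,
                                      stringsAsFactors = FALSE),
                           n_haplotypes, n_specimens, id_prefix = "RUM")
  model_b <- species_model("cresphontes", paste(chars_b, collapse = ""),
                           data.frame(position = sites$position,
                                      state = sites$state_b,
                                      stringsAsFactors = FALSE),
                           n_haplotypes, n_specimens, id_prefix = "CRE")
  list(model_a = model_a, model_b = model_b,
       sites = data.frame(position = sites$position,
                          state_a = sites$state_a, state_b = sites$state_b,
                          stringsAsFactors = FALSE))
}

# Integer haplotype counts from weights: largest-remainder apportionment
# with a floor of 1 so every modeled haplotype is realized.
.apportion_counts <- function(weights, n) {
  k <- length(weights)
  if (n < k) stop("model demands more haplotypes (", k,
                  ") than specimens (", n, ")")
  raw <- weights / sum(weights) * n
  counts <- pmax(1L, floor(raw))
  while (sum(counts) > n) {
    over <- which(counts > 1L)
    drop <- over[which.min((raw - counts)[over])]
    counts[drop] <- counts[drop] - 1L
  }
  while (sum(counts) < n) {
    add <- which.max(raw - counts)
    counts[add] <- counts[add] + 1L
  }
  as.integer(counts)
}

# Build haplotype sequences for one species: the modal haplotype plus
# (k-2) single-substitution variants and one double-substitution variant,
# so pairwise distances are 1-3 substitutions.
.build_haplotypes <- function(model, allowed_positions) {
  k <- model$n_haplotypes
  chars <- seq_chars(model$base_sequence)
  L <- length(chars)
  n_subs <- if (k <= 1L) integer(0)
            else if (k == 2L) 1L
            else c(rep(1L, k - 2L), 2L)
  max_pair <- if (k <= 1L) 0L else if (k == 2L) 1L else 3L
  if (max_pair > floor(model$within_cap * L)) {
    stop("model demands more haplotypes than achievable within the ",
         "within-species distance cap")
  }
  need <- sum(n_subs)
  if (need > length(allowed_positions)) {
    stop("not enough mutable positions for ", k, " haplotypes")
  }
  pos_pool <- sample(allowed_positions, need)
  haps <- vector("list", k)
  haps[[1]] <- chars
  used <- 0L
  for (h in seq_len(k - 1L)) {
    v <- chars
    for (m in seq_len(n_subs[h])) {
      used <- used + 1L
      p <- pos_pool[used]
      v[p] <- sample(setdiff(UNAMBIG, chars[p]), 1L)
    }
    haps[[h + 1L]] <- v
  }
  vapply(haps, paste, character(1), collapse = "")
}

#' Simulate a two-species barcode population
#'
#' Deterministic given the seed. Emits full-length records for both species
#' plus truth tables: the planted diagnostic sites, each specimen's
#' haplotype, and the group labels.
#'
#' @param model_a,model_b \code{species_model}s; their planted sites must
#'   share positions and differ in state at every position. Defaults: the
#'   packaged study-mirroring pair of \code{\link{default_species_pair}}.
#' @param seed integer RNG seed (mandatory).
#' @return list: \code{records} (barcode_set), \code{truth} with
#'   \code{sites} (position, state_a, state_b), \code{haplotypes}
#'   (specimen_id, group, haplotype), \code{labels} (named vector
#'   specimen_id -> group).
#' @export
simulate_barcodes <- function(model_a = NULL, model_b = NULL, seed) {
  if (is.null(model_a) || is.null(model_b)) {
    pair <- default_species_pair()
    if (is.null(model_a)) model_a <- pair$model_a
    if (is.null(model_b)) model_b <- pair$model_b
  }
  pa <- model_a$planted_sites[order(model_a$planted_sites$position), ]
  pb <- model_b$planted_sites[order(model_b$planted_sites$position), ]
  if (!identical(pa$position, pb$position) || any(pa$state == pb$state)) {
    stop("planted sites of the two models must share positions and ",
         "differ in state")
  }
  set.seed(as.integer(seed))
  L <- nchar(model_a$base_sequence)
  allowed <- setdiff(seq_len(L), c(pa$position, ID_TAG_ASSAY_REGION))

  sim_one <- function(model) {
    haps <- .build_haplotypes(model, allowed)
    counts <- .apportion_counts(model$haplotype_weights, model$n_specimens)
    hap_idx <- rep(seq_along(haps), counts)
    ids <- sprintf("%s-%03d", model$id_prefix, seq_len(model$n_specimens))
    list(records = new_barcode_set(ids, model$name, "", "full",
                                   haps[hap_idx]),
         haplotypes = data.frame(specimen_id = ids, group = model$name,
                                 haplotype = sprintf("%s-H%02d",
                                                     model$id_prefix,
                                                     hap_idx),
                                 stringsAsFactors = FALSE))
  }
  a <- sim_one(model_a)
  b <- sim_one(model_b)
  records <- rbind(a$records, b$records)
  class(records) <- c("barcode_set", "data.frame")
  haplotypes <- rbind(a$haplotypes, b$haplotypes)
  labels <- stats::setNames(haplotypes$group, haplotypes$specimen_id)
  list(records = records,
       truth = list(sites = data.frame(position = pa$position,
                                       state_a = pa$state,
                                       state_b = pb$state,
                                       stringsAsFactors = FALSE),
                    haplotypes = haplotypes, labels = labels))
}

#' Degrade simulated records to ID tags and partial barcodes
#'
#' Replaces a seeded random fraction of records by their primer-free ID-tag
#' insert (completeness "id_tag") and another fraction by their 5' 443-bp
#' partial (completeness "partial"), mimicking what old museum specimens
#' yield.
#'
#' @param records a full-length \code{barcode_set}.
#' @param fwd,rev the ID-tag primer pair (default the packaged
#'   swtl-ID1F/swtl-ID1R).
#' @param dropout fraction of records reduced to ID tags.
#' @param partial_fraction fraction reduced to 443-bp partials.
#' @param seed integer RNG seed.
#' @return the degraded \code{barcode_set} (same order) with a
#'   \code{degradation} truth data frame in \code{attr(, "truth")}.
#' @export
simulate_id_tags <- function(records, fwd = NULL, rev = NULL, dropout,
                             partial_fraction = 0, seed) {
  if (is.null(fwd) || is.null(rev)) {
    ps <- published_primers()
    if (is.null(fwd)) fwd <- ps[["swtl-ID1F"]]
    if (is.null(rev)) rev <- ps[["swtl-ID1R"]]
  }
  set.seed(as.integer(seed))
  n <- nrow(records)
  n_tag <- round(dropout * n)
  n_part <- round(partial_fraction * n)
  if (n_tag + n_part > n) stop("dropout + partial_fraction exceed 1")
  pick <- sample.int(n, n_tag + n_part)
  tag_idx <- pick[seq_len(n_tag)]
  part_idx <- pick[setdiff(seq_along(pick), seq_len(n_tag))]
  degradation <- rep("none", n)
  offsets <- rep(0L, n)
  for (i in tag_idx) {
    tag <- extract_id_tag(records$sequence[i], fwd, rev,
                          records$specimen_id[i])
    records$sequence[i] <- tag$sequence[1]
    records$completeness[i] <- "id_tag"
    offsets[i] <- attr(tag, "frame_offset")
    degradation[i] <- "id_tag"
  }
  for (i in part_idx) {
    records$sequence[i] <- substr(records$sequence[i], 1L, 443L)
    records$completeness[i] <- "partial"
    degradation[i] <- "partial"
  }
  attr(records, "truth") <- data.frame(
    specimen_id = records$specimen_id, degradation = degradation,
    frame_offset = offsets, stringsAsFactors = FALSE)
  records
}

#' Specify the morphometric generating model
#'
#' Per-group uniform generating intervals for the U-B angle and for each
#' ratio entering the composite scores (raw distances are reconstructed
#' from the drawn ratios); YL is constant within each group. Defaults put
#' the two groups' composite-score supports provably apart, and hybrid
#' mixes (convex combinations of one parental draw from each group,
#' lambda in \code{hybrid_lambda}) provably between the parental ranges on
#' the genitalic axis.
#'
#' @param groups names of the two groups.
#' @param intervals named list per group: angle, r1 ((B-A)/(C-B)), gh
#'   (G/H), fp (F/P), tv (T/V), wd (W/D) two-element ranges and scalar YL.
#' @param hybrid_fraction hybrids to append, as a fraction of the pure
#'   cohort size.
#' @param hybrid_lambda mixing-weight range for hybrids.
#' @return a \code{morpho_model} list.
#' @export
morpho_model <- function(groups = c("rumiko", "cresphontes"),
                         intervals = NULL, hybrid_fraction = 0,
                         hybrid_lambda = c(0.45, 0.55)) {
  if (is.null(intervals)) {
    intervals <- list(
      list(angle = c(1.4, 1.6), r1 = c(0.9, 1.3), gh = c(0.9, 1.3),
           YL = 1, fp = c(0.9, 1.3), tv = c(0.9, 1.3), wd = c(0.8, 1.6)),
      list(angle = c(0.2, 0.4), r1 = c(0.3, 0.7), gh = c(0.3, 0.7),
           YL = 0, fp = c(0.3, 0.7), tv = c(0.3, 0.7), wd = c(0.4, 1.2)))
    names(intervals) <- groups
  }
  for (g in groups) {
    iv <- intervals[[g]]
    if (any(c(iv$r1, iv$gh, iv$fp, iv$tv, iv$wd) <= 0)) {
      stop("ratio intervals must be positive (zero denominators otherwise)")
    }
    if (any(iv$angle < 0 | iv$angle > pi)) stop("angle interval outside [0, pi]")
  }
  structure(list(groups = groups, intervals = intervals,
                 hybrid_fraction = hybrid_fraction,
                 hybrid_lambda = hybrid_lambda),
            class = "morpho_model")
}

# One specimen's raw measures from drawn ratios.
.draw_raw <- function(iv) {
  runif_in <- function(r) stats::runif(1L, r[1], r[2])
  u <- stats::runif(1L, 0.5, 1)
  A <- stats::runif(1L, 1, 2)
  B <- A + u
  C <- B + u / runif_in(iv$r1)
  H <- stats::runif(1L, 1, 2)
  P <- stats::runif(1L, 1, 2)
  V <- stats::runif(1L, 1, 2)
  D <- stats::runif(1L, 1, 2)
  c(ub_angle_rad = runif_in(iv$angle), A = A, B = B, C = C,
    G = runif_in(iv$gh) * H, H = H, YL = iv$YL,
    F = runif_in(iv$fp) * P, P = P, T = runif_in(iv$tv) * V, V = V,
    W = runif_in(iv$wd) * D, D = D)
}

#' Simulate a morphometric cohort
#'
#' Deterministic given the seed. With the default model and
#' \code{hybrid_fraction = 0}, both composite-score supports are disjoint
#' by construction, so \code{\link{hiatus_test}} reports separation on both
#' axes. Hybrids are appended as convex mixes of one parental draw from
#' each group (YL follows the majority parent) and flagged via
#' \code{is_hybrid}; their true_label is the majority parent.
#'
#' @param model a \code{morpho_model}.
#' @param n_per_group pure specimens per group.
#' @param seed integer RNG seed.
#' @return a \code{morpho_records} data frame with true_label, is_hybrid
#'   and composite scores.
#' @export
simulate_morphometrics <- function(model = morpho_model(), n_per_group,
                                   seed) {
  set.seed(as.integer(seed))
  ga <- model$groups[1]; gb <- model$groups[2]
  rows <- list()
  for (g in model$groups) {
    for (i in seq_len(n_per_group)) {
      raw <- .draw_raw(model$intervals[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sprintf("%s-M%03d", toupper(substr(g, 1, 3)), i),
        t(raw), true_label = g, is_hybrid = FALSE, stringsAsFactors = FALSE)
    }
  }
  n_h <- round(model$hybrid_fraction * 2L * n_per_group)
  for (i in seq_len(n_h)) {
    raw_a <- .draw_raw(model$intervals[[ga]])
    raw_b <- .draw_raw(model$intervals[[gb]])
    lam <- stats::runif(1L, model$hybrid_lambda[1], model$hybrid_lambda[2])
    raw <- lam * raw_a + (1 - lam) * raw_b
    raw["YL"] <- if (lam > 0.5) model$intervals[[ga]]$YL
                 else model$intervals[[gb]]$YL
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = sprintf("HYB-M%03d", i), t(raw),
      true_label = if (lam > 0.5) ga else gb, is_hybrid = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    df <- data.frame(specimen_id = character(), stringsAsFactors = FALSE)
    for (col in MORPHO_COLUMNS) df[[col]] <- numeric(0)
    df$true_label <- character(0)
    df$is_hybrid <- logical(0)
    df$g_score <- numeric(0)
    df$f_score <- numeric(0)
    class(df) <- c("morpho_records", "data.frame")
    return(df)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  morpho_scores(df)
}
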