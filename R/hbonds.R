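# ---------------------------------------------------------------------------
# Hydrogen-bond detection and static/dynamic/persistency bookkeeping
# ---------------------------------------------------------------------------

# Class label from the donor/acceptor atoms' solute and mainchain flags.
hb_class_label <- function(at, d, a) {
  ds <- at$is_solute[d]; as_ <- at$is_solute[a]
  if (ds && as_) {
    if (at$is_mainchain[d] && at$is_mainchain[a]) return("M-M")
    if (!at$is_mainchain[d] && !at$is_mainchain[a]) return("S-S")
    return("M-S")
  }
  prot <- if (ds) d else a
  if (at$is_mainchain[prot]) "M-solv" else "S-solv"
}

#' Detect hydrogen bonds in a single frame
#'
#' A bond is reported for every (donor, attached hydrogen, acceptor)
#' triple with donor-acceptor distance `<= hb_distance_cutoff` (3.5
#' Angstrom by default) and donor-hydrogen-acceptor angle (vertex at the
#' hydrogen) `>= hb_angle_cutoff` (120 degrees), both inclusive. Mainchain
#' amide hydrogens absent from the structure are placed geometrically;
#' other donors without hydrogens fall back to a distance-only criterion
#' with a warning (disable with `allow_distance_only = FALSE`). Distances
#' use the minimum-image convention when `box` is given.
#'
#' @param coords N x 3 frame coordinates (Angstrom).
#' @param sys An [sd_system()].
#' @param config An [analysis_config()].
#' @param scope `"intra-protein"` (both partners solute),
#'   `"protein-solvent"` (one partner solute, one water; water-water bonds
#'   are never reported), or `"all"` (both, still excluding water-water).
#' @param box Optional length-3 orthorhombic box (Angstrom).
#' @param allow_distance_only Permit hydrogen-less side-chain donors via
#'   the distance criterion alone (default `TRUE`).
#' @return Data frame with columns `donor`, `hydrogen` (`NA` for
#'   distance-only donors), `acceptor`, `class`, ordered by (donor,
#'   hydrogen, acceptor).
#' @export
detect_hbonds_frame <- function(coords, sys, config = analysis_config(),
                                scope = c("all", "intra-protein",
                                          "protein-solvent"),
                                box = NULL, allow_distance_only = TRUE) {
  scope <- match.arg(scope)
  at <- sys$atoms
  dcut <- config$hb_distance_cutoff
  acut <- config$hb_angle_cutoff
  don <- which(at$donor)
  acc <- which(at$acceptor)
  if (scope == "intra-protein") {
    don <- don[at$is_solute[don]]; acc <- acc[at$is_solute[acc]]
  }
  out_d <- integer(0); out_h <- integer(0); out_a <- integer(0)
  warned <- FALSE
  bb <- NULL
  for (d in don) {
    hs <- sys$h_attached[[d]]
    inferred_h <- NULL
    if (!length(hs)) {
      if (at$name[d] == "N" && at$is_mainchain[d]) {
        if (is.null(bb)) bb <- backbone_index(sys)
        r <- match(at$resid[d], bb$resid)
        if (!is.na(r) && r > 1L && !anyNA(c(bb$CA[r], bb$C[r - 1L]))) {
          inferred_h <- infer_amide_h(coords, d, bb$CA[r], bb$C[r - 1L])
        } else next  # N-terminal nitrogen without resolvable H
      } else if (!allow_distance_only) {
        stop(sprintf("donor atom %d (%s) has no attached or inferable hydrogen",
                     d, at$name[d]))
      } else {
        if (!warned) {
          warning("donor(s) without hydrogens: using distance-only criterion")
          warned <- TRUE
        }
      }
    }
    d2 <- dist2_point(coords[d, ], coords[acc, , drop = FALSE], box)
    cand <- acc[d2 <= dcut^2 & d2 > 1.8^2 & acc != d]
    if (!length(cand)) next
    if (length(hs)) {
      for (h in hs) {
        hv <- coords[h, ]
        v1 <- min_image(coords[d, ] - hv, box)
        for (a in cand) {
          v2 <- min_image(coords[a, ] - hv, box)
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          if (ang >= acut - 1e-9) {
            out_d <- c(out_d, d); out_h <- c(out_h, h); out_a <- c(out_a, a)
          }
        }
      }
    } else if (!is.null(inferred_h)) {
      v1 <- min_image(coords[d, ] - inferred_h, box)
      for (a in cand) {
        v2 <- min_image(coords[a, ] - inferred_h, box)
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= acut - 1e-9) {
          out_d <- c(out_d, d); out_h <- c(out_h, NA_integer_)
          out_a <- c(out_a, a)
        }
      }
    } else {
      out_d <- c(out_d, d)
      out_h <- c(out_h, rep(NA_integer_, length(cand)))
      out_a <- c(out_a, cand)
    }
  }
  res <- data.frame(donor = out_d, hydrogen = out_h, acceptor = out_a,
                    stringsAsFactors = FALSE)
  if (nrow(res)) {
    keep <- vapply(seq_len(nrow(res)), function(i) {
      ds <- at$is_solute[res$donor[i]]; as_ <- at$is_solute[res$acceptor[i]]
      if (scope == "intra-protein") ds && as_
      else if (scope == "protein-solvent") xor(ds, as_)
      else ds || as_   # drop water-water
    }, logical(1))
    res <- res[keep, , drop = FALSE]
  }
  if (nrow(res)) {
    res$class <- vapply(seq_len(nrow(res)), function(i)
      hb_class_label(at, res$donor[i], res$acceptor[i]), character(1))
    o <- order(res$donor, res$hydrogen, res$acceptor, na.last = FALSE)
    res <- res[o, , drop = FALSE]
    rownames(res) <- NULL
  } else {
    res$class <- character(0)
  }
  res
}

#' Hydrogen-bond statistics over a trajectory
#'
#' Static mean = per-frame bond count averaged over frames; dynamic count
#' = number of distinct (donor, hydrogen, acceptor) triples seen in at
#' least one frame; persistency of a bond = percentage of frames in which
#' it exists. The identity `sum(persistency)/100 == static_mean` holds
#' exactly by construction. Intra-protein bonds are classed `M-M`, `M-S`,
#' `S-S` by the mainchain flags of donor and acceptor; protein-solvent
#' bonds are `M-solv` / `S-solv` by the protein partner's flag.
#'
#' @param traj An [sd_trajectory()].
#' @param config An [analysis_config()].
#' @param scope `"intra-protein"` or `"protein-solvent"`.
#' @param ... Passed to [detect_hbonds_frame()].
#' @return Object of class `sd_hbond_stats`: `static_mean`, `static_sd`,
#'   `dynamic_count`, `mean_persistency`, `bonds` (per-bond data frame
#'   with `persistency` in %), `class_counts`, `class_mean_persistency`,
#'   `class_static_mean`, `n_frames`.
#' @export
hbond_statistics <- function(traj, config = analysis_config(),
                             scope = c("intra-protein", "protein-solvent"),
                             ...) {
  scope <- match.arg(scope)
  sys <- traj$system
  if (scope == "protein-solvent" && all(sys$atoms$is_solute)) {
    stop("protein-solvent scope requested but the system has no solvent atoms")
  }
  f <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  classes <- new.env(parent = emptyenv())
  per_frame <- integer(f)
  for (k in seq_len(f)) {
    box <- if (is.null(traj$box)) NULL else traj$box[k, ]
    hb <- detect_hbonds_frame(frame_coords(traj, k), sys, config,
                              scope = scope, box = box, ...)
    per_frame[k] <- nrow(hb)
    if (nrow(hb)) {
      keys <- paste(hb$donor, hb$hydrogen, hb$acceptor, sep = "_")
      for (i in seq_along(keys)) {
        key <- keys[i]
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
        classes[[key]] <- hb$class[i]
      }
    }
  }
  keys <- ls(counts)
  nb <- length(keys)
  bonds <- if (nb) {
    parts <- strsplit(keys, "_")
    data.frame(
      donor = as.integer(vapply(parts, `[`, character(1), 1L)),
      hydrogen = suppressWarnings(
        as.integer(vapply(parts, `[`, character(1), 2L))),
      acceptor = as.integer(vapply(parts, `[`, character(1), 3L)),
      class = vapply(keys, function(k) classes[[k]], character(1)),
      n_present = vapply(keys, function(k) counts[[k]], integer(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), class = character(0),
               n_present = integer(0))
  }
  bonds$persistency <- 100 * bonds$n_present / f
  bonds <- bonds[order(bonds$donor, bonds$hydrogen, bonds$acceptor,
                       na.last = FALSE), , drop = FALSE]
  rownames(bonds) <- NULL
  cls <- sort(unique(bonds$class))
  structure(list(
    scope = scope,
    static_mean = mean(per_frame),
    static_sd = if (f > 1L) sd(per_frame) else 0,
    dynamic_count = nb,
    mean_persistency = if (nb) mean(bonds$persistency) else NA_real_,
    bonds = bonds,
    per_frame = per_frame,
    n_frames = f,
    class_counts = vapply(cls, function(cl) sum(bonds$class == cl),
                          integer(1)),
    class_mean_persistency = vapply(cls, function(cl)
      mean(bonds$persistency[bonds$class == cl]), numeric(1)),
    class_static_mean = vapply(cls, function(cl)
      sum(bonds$n_present[bonds$class == cl]) / f, numeric(1))
  ), class = "sd_hbond_stats")
}

#' @export
print.sd_hbond_stats <- function(x, ...) {
  cat(sprintf("sd_hbond_stats (%s): static %.2f +/- %.2f, dynamic %d, mean persistency %.2f%%\n",
              x$scope, x$static_mean, x$static_sd, x$dynamic_count,
              x$mean_persistency))
  if (length(x$class_counts)) {
    cat("  class counts:",
        paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write per-bond persistency list as TSV
#' @param stats An `sd_hbond_stats`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hbond_stats <- function(stats, path) {
  utils::write.table(stats$bonds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
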