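#' Dice similarity coefficient of two binary masks
#'
#' `DSC(X, Y) = 2 |X intersect Y| / (|X| + |Y|)` where `|X|` counts 1-valued
#' pixels. Two empty masks are defined to agree perfectly (DSC 1): sections
#' free of a structure should not be penalised.
#'
#' @param x,y binary matrices of equal shape.
#' @export
dice <- function(x, y) {
  assert_same_shape(x, y, "masks")
  s <- sum(x) + sum(y)
  if (s == 0) return(1)
  2 * sum(x * y) / s
}

#' Combined vasculature and epithelium mask
#'
#' The pixel-wise Boolean OR of the vasculature and nasal-epithelium masks
#' of one section; this combined mask drives all Dice-based registration
#' choices because the two structures are relatively continuous along the
#' specimen.
#'
#' @param vasculature_mask,epithelium_mask binary matrices of equal shape.
#' @export
combined_mask <- function(vasculature_mask, epithelium_mask) {
  assert_same_shape(vasculature_mask, epithelium_mask, "masks")
  assert_binary(vasculature_mask, "vasculature mask")
  assert_binary(epithelium_mask, "epithelium mask")
  (vasculature_mask + epithelium_mask > 0) * 1
}

section_combined <- function(s) combined_mask(s$masks$vasculature,
                                              s$masks$nasal_epithelium)

#' Partition included sections into contiguous blocks
#'
#' @param included_indices sorted ascending indices of included sections.
#' @param block_size sections per block (default 5); the final block keeps
#'   the remainder.
#' @return A list of blocks, each a list with `k` (block number) and
#'   `section_indices`.
#' @export
partition_blocks <- function(included_indices, block_size = 5L) {
  if (length(included_indices) == 0) stop_olf("no included sections to partition")
  if (is.unsorted(included_indices, strictly = TRUE))
    stop_olf("included_indices must be sorted strictly ascending")
  grp <- ceiling(seq_along(included_indices) / block_size)
  lapply(unique(grp), function(k)
    list(k = k, section_indices = included_indices[grp == k]))
}

#' Select the intra-block reference section
#'
#' The reference is the block member maximising the sum of pairwise Dice
#' coefficients of the combined masks against all block members (the
#' self-term, Dice 1, enters uniformly). Ties resolve to the lowest index.
#'
#' @param combined_masks named list of combined masks, names = section
#'   indices.
#' @return The reference section index (integer).
#' @export
select_intrablock_reference <- function(combined_masks) {
  n <- length(combined_masks)
  if (n == 0) stop_olf("empty block")
  idx <- as.integer(names(combined_masks))
  score <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n), function(j)
      dice(combined_masks[[i]], combined_masks[[j]]), numeric(1))),
    numeric(1))
  idx[which.max(score)]  # which.max takes the first (lowest-index) maximum
}

#' Select the inter-block interface pair
#'
#' Exhaustive argmax of the combined-mask Dice coefficient over all cross
#' pairs between two consecutive blocks; ties resolve to the
#' lexicographically smallest `(i, j)`. The anterior-block member acts as
#' the fixed section.
#'
#' @param masks_anterior,masks_posterior named lists of combined masks
#'   (names = section indices) of the two registered blocks.
#' @return Named integer vector `c(i = ..., j = ...)`.
#' @export
select_interblock_pair <- function(masks_anterior, masks_posterior) {
  ia <- as.integer(names(masks_anterior)); ib <- as.integer(names(masks_posterior))
  best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
  for (i in order(ia)) {
    for (j in order(ib)) {
      d <- dice(masks_anterior[[i]], masks_posterior[[j]])
      if (d > best) { best <- d; bi <- ia[i]; bj <- ib[j] }
    }
  }
  c(i = bi, j = bj)
}

#' Linear interpolation of an interface displacement field
#'
#' For `N` sections spanning a block interface, the i-th field is the
#' fraction `(i - 1) / N` of the interface field, so the displacement ramps
#' linearly across the interface.
#'
#' @param phi the interface `displacement_field`.
#' @param N number of interpolated sections (>= 1).
#' @return A list of `N` `displacement_field`s.
#' @export
interblock_interpolate <- function(phi, N) {
  if (N <= 0) stop_olf("N must be at least 1")
  lapply(seq_len(N), function(i) scale_field(phi, (i - 1) / N))
}

#' Registration configuration
#'
#' @param rigid_levels,bspline_levels multiresolution pyramid depths for
#'   the rigid and B-spline intensity stages. Depths are capped so that the
#'   coarsest level keeps at least `min_size` px in each dimension; set
#'   `bspline_levels = 0` to skip the deformable intensity stage.
#' @param mask_levels pyramid depth of the mask-based refinement (0 skips
#'   it); kept shallow so the refinement focuses on small structures and
#'   cannot undo the intensity stage.
#' @param similarity similarity for the intensity stage, `"mi"` (mutual
#'   information averaged over channels) or `"ncc"`.
#' @param mask_similarity similarity for the mask stage (masks are treated
#'   as intensities); default `"ncc"`.
#' @param transform `"rigid"` (rotation + translation) or `"translation"`.
#' @param grid_size B-spline control grid (per side, >= 4).
#' @param max_iterations optimiser iteration cap per rigid level.
#' @param bspline_iterations optimiser iteration cap per B-spline level.
#' @param min_size minimum image side at the coarsest pyramid level, px.
#' @export
registration_config <- function(rigid_levels = 4L, bspline_levels = 4L,
                                mask_levels = 3L,
                                similarity = c("mi", "ncc"),
                                mask_similarity = c("ncc", "mi"),
                                transform = c("rigid", "translation"),
                                grid_size = 4L, max_iterations = 150L,
                                bspline_iterations = 15L, min_size = 16L) {
  if (rigid_levels < 1) stop_olf("rigid_levels must be >= 1")
  if (mask_levels > max(bspline_levels, rigid_levels))
    stop_olf("mask_levels must not exceed the intensity pyramid depth")
  structure(list(rigid_levels = rigid_levels, bspline_levels = bspline_levels,
                 mask_levels = mask_levels,
                 similarity = match.arg(similarity),
                 mask_similarity = match.arg(mask_similarity),
                 transform = match.arg(transform),
                 grid_size = as.integer(grid_size),
                 max_iterations = max_iterations,
                 bspline_iterations = bspline_iterations,
                 min_size = as.integer(min_size)),
            class = "registration_config")
}

cap_levels <- function(levels, shape, min_size) {
  cap <- max(1L, floor(log2(min(shape) / min_size)) + 1L)
  min(levels, cap)
}

mean_similarity <- function(fixed_list, warped_list, sim)
  mean(mapply(sim, fixed_list, warped_list))

# Rigid (or translation-only) multiresolution registration on channel lists.
register_rigid <- function(fixed_list, moving_list, config) {
  sim <- similarity_fun(config$similarity)
  shape <- dim(fixed_list[[1]])
  levels <- cap_levels(config$rigid_levels, shape, config$min_size)
  par <- if (config$transform == "rigid") c(0, 0, 0) else c(0, 0)
  first <- TRUE
  for (lev in seq(levels - 1, 0)) {
    f <- 2^lev
    fx <- lapply(fixed_list, pyr_level, lev)
    mv <- lapply(moving_list, pyr_level, lev)
    lshape <- dim(fx[[1]])
    if (first) {
      # exhaustive integer-translation search at the coarsest level: the
      # similarity basin is narrow, a grid start keeps the optimiser in it
      R <- max(2L, round(min(lshape) / 4))
      best <- c(0, 0); bestv <- Inf
      for (tr in -R:R) {
        for (tc in -R:R) {
          fld <- rigid_field(0, tr, tc, lshape)
          w <- lapply(mv, function(m) .warp_kernel(m, fld$r, fld$c, FALSE))
          v <- -mean_similarity(fx, w, sim)
          if (v < bestv) { bestv <- v; best <- c(tr, tc) }
        }
      }
      if (config$transform == "rigid") par <- c(0, best * f)
      else par <- best * f
      first <- FALSE
    }
    obj <- function(p) {
      fld <- if (config$transform == "rigid")
        rigid_field(p[1], p[2], p[3], lshape)
      else rigid_field(0, p[1], p[2], lshape)
      w <- lapply(mv, function(m) .warp_kernel(m, fld$r, fld$c, FALSE))
      -mean_similarity(fx, w, sim)
    }
    p0 <- par
    ti <- if (config$transform == "rigid") 2:3 else 1:2
    p0[ti] <- p0[ti] / f
    opt <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = config$max_iterations, reltol = 1e-9))
    par <- opt$par
    par[ti] <- par[ti] * f
  }
  if (config$transform == "rigid")
    list(par = par, field = rigid_field(par[1], par[2], par[3], shape))
  else
    list(par = c(0, par), field = rigid_field(0, par[1], par[2], shape))
}

# B-spline refinement on (already pre-warped) image lists; returns the
# residual deformable field at full resolution.
register_bspline <- function(fixed_list, moving_list, config, levels,
                             similarity) {
  sim <- similarity_fun(similarity)
  shape <- dim(fixed_list[[1]])
  levels <- cap_levels(levels, shape, config$min_size)
  G <- max(4L, config$grid_size)
  npar <- 2L * G * G
  par <- numeric(npar)
  for (lev in seq(levels - 1, 0)) {
    fx <- lapply(fixed_list, pyr_level, lev)
    mv <- lapply(moving_list, pyr_level, lev)
    lshape <- dim(fx[[1]])
    f <- 2^lev
    obj <- function(p) {
      fr <- .bspline_field_kernel(matrix(p[1:(G * G)] / f, G, G),
                                  lshape[1], lshape[2])
      fc <- .bspline_field_kernel(matrix(p[(G * G + 1):npar] / f, G, G),
                                  lshape[1], lshape[2])
      w <- lapply(mv, function(m) .warp_kernel(m, fr, fc, FALSE))
      -mean_similarity(fx, w, sim)
    }
    opt <- optim(par, obj, method = "BFGS",
                 control = list(maxit = config$bspline_iterations,
                                reltol = 1e-8, ndeps = rep(0.1, npar)))
    par <- opt$par
  }
  bspline_field(matrix(par[1:(G * G)], G, G),
                matrix(par[(G * G + 1):npar], G, G), shape)
}

#' Intensity-based pair registration
#'
#' Registers the four channels of a moving section onto a fixed section: a
#' rigid registration followed by a B-spline free-form refinement, both
#' driven by a multiresolution pyramid and (by default) per-channel mutual
#' information averaged over the four channels.
#'
#' @param fixed_channels,moving_channels named lists of four channel
#'   matrices.
#' @param config a [registration_config()].
#' @return A `displacement_field` mapping the moving onto the fixed section.
#' @export
register_pair_intensity <- function(fixed_channels, moving_channels, config) {
  for (m in c(fixed_channels, moving_channels))
    if (!all(is.finite(m))) stop_olf("non-finite intensities in registration input")
  rig <- register_rigid(fixed_channels, moving_channels, config)
  if (config$bspline_levels < 1) return(rig$field)
  pre <- lapply(moving_channels, function(m)
    .warp_kernel(m, rig$field$r, rig$field$c, FALSE))
  bsp <- register_bspline(fixed_channels, pre, config, config$bspline_levels,
                          config$similarity)
  compose_fields(rig$field, bsp)
}

#' Mask-based pair refinement
#'
#' Refines an intensity-stage displacement field using only the combined
#' vasculature/epithelium masks, registered as intensities with a shallow
#' (default three-level) B-spline pyramid. An empty fixed mask leaves the
#' initial field untouched (with a warning): there is nothing to refine
#' against, and skipping cannot degrade the result.
#'
#' @param fixed_combined,moving_combined combined masks (see
#'   [combined_mask()]).
#' @param init_field `displacement_field` from the intensity stage.
#' @param config a [registration_config()].
#' @return The composed `displacement_field`.
#' @export
register_pair_mask <- function(fixed_combined, moving_combined, init_field,
                               config) {
  if (config$mask_levels < 1) return(init_field)
  if (sum(fixed_combined) == 0) {
    warning("empty fixed combined mask: mask refinement skipped")
    return(init_field)
  }
  pre <- .warp_kernel(moving_combined, init_field$r, init_field$c, FALSE)
  bsp <- register_bspline(list(fixed_combined), list(pre), config,
                          config$mask_levels, config$mask_similarity)
  refined <- compose_fields(init_field, bsp)
  # the refinement must not undo the intensity stage: keep it only if the
  # combined-mask Dice does not decrease
  d0 <- dice(fixed_combined,
             .warp_kernel(moving_combined, init_field$r, init_field$c, TRUE))
  d1 <- dice(fixed_combined,
             .warp_kernel(moving_combined, refined$r, refined$c, TRUE))
  if (d1 >= d0) refined else init_field
}

warp_section <- function(s, field) {
  chans <- lapply(s$channels, apply_field, field = field, mode = "linear")
  masks <- lapply(s$masks, apply_field, field = field, mode = "nearest")
  section_record(s$index, chans, masks, included = s$included)
}

#' Register one block of sections
#'
#' Chooses the intra-block reference by the sum-of-Dice rule, registers
#' every other block member onto it (intensity stage then mask refinement),
#' and warps channels and all six masks once with the composed field.
#'
#' @param sections list of `section_record`s forming the block.
#' @param config a [registration_config()].
#' @return A list with `sections` (warped), `fields` (per section index),
#'   and `reference_index`.
#' @export
register_block <- function(sections, config) {
  cm <- lapply(sections, section_combined)
  names(cm) <- vapply(sections, function(s) s$index, integer(1))
  ref_idx <- select_intrablock_reference(cm)
  ref <- sections[[match(ref_idx, as.integer(names(cm)))]]
  out <- vector("list", length(sections))
  fields <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    if (s$index == ref_idx) {
      out[[i]] <- s
      fields[[i]] <- zero_field(dim(s$channels[[1]]))
      next
    }
    fld <- tryCatch({
      fi <- register_pair_intensity(ref$channels, s$channels, config)
      register_pair_mask(cm[[as.character(ref_idx)]],
                         cm[[as.character(s$index)]], fi, config)
    }, error = function(e)
      stop_olf("registration failed for section %d: %s", s$index,
               conditionMessage(e)))
    out[[i]] <- warp_section(s, fld)
    fields[[i]] <- fld
  }
  names(fields) <- names(cm)
  list(sections = out, fields = fields, reference_index = ref_idx)
}

#' Register a full section series
#'
#' `method = "block"` performs the two-step anatomy-based registration:
#' included sections are partitioned into contiguous blocks (default five
#' sections) that are registered independently, then consecutive block
#' interfaces are bridged anterior-to-posterior by registering the most
#' similar cross pair and applying linearly interpolated fractions of the
#' interface field to the sections spanning the interface. Each block keeps
#' its own reference frame, so genuine curvature of the specimen is
#' preserved rather than straightened. `method = "sequential"` registers
#' every included section onto its (already registered) predecessor, the
#' naive scheme that straightens curved structures (the "banana effect").
#'
#' @param series a `section_series` with at least two included sections.
#' @param config a [registration_config()].
#' @param method `"block"` or `"sequential"`.
#' @param block_size sections per block.
#' @return A list with `series` (registered), `fields` (list of composed
#'   `displacement_field`s indexed by section index as character), and for
#'   the block method `blocks` (per-block reference indices).
#' @export
register_series <- function(series, config = registration_config(),
                            method = c("block", "sequential"),
                            block_size = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(series, "section_series"))
  inc <- included_indices(series)
  if (length(inc) < 2) stop_olf("need at least 2 included sections")
  pos <- match(inc, vapply(series$sections, function(s) s$index, integer(1)))
  recs <- series$sections
  shape <- dim(recs[[pos[1]]]$channels[[1]])
  fields <- stats::setNames(rep(list(zero_field(shape)), length(inc)),
                            as.character(inc))

  if (method == "sequential") {
    for (m in 2:length(inc)) {
      fixed <- recs[[pos[m - 1]]]
      mov <- recs[[pos[m]]]
      fi <- register_pair_intensity(fixed$channels, mov$channels, config)
      fld <- register_pair_mask(section_combined(fixed), section_combined(mov),
                                fi, config)
      recs[[pos[m]]] <- warp_section(mov, fld)
      fields[[as.character(inc[m])]] <- fld
    }
    out <- series
    out$sections <- recs
    return(list(series = out, fields = fields, method = method))
  }

  blocks <- partition_blocks(inc, block_size)
  regs <- lapply(blocks, function(b)
    register_block(recs[pos[match(b$section_indices, inc)]], config))
  for (bi in seq_along(blocks)) {
    for (si in seq_along(blocks[[bi]]$section_indices)) {
      idx <- blocks[[bi]]$section_indices[si]
      recs[[pos[match(idx, inc)]]] <- regs[[bi]]$sections[[si]]
      fields[[as.character(idx)]] <- regs[[bi]]$fields[[si]]
    }
  }

  # Interface smoothing, sequential anterior -> posterior. The posterior
  # block's sections anterior to the selected moving section receive
  # linearly decaying fractions of the interface field; the moving section
  # and everything posterior stay in their block frame.
  for (k in seq_len(length(blocks) - 1)) {
    idxA <- blocks[[k]]$section_indices
    idxB <- blocks[[k + 1]]$section_indices
    cmA <- lapply(idxA, function(i) section_combined(recs[[pos[match(i, inc)]]]))
    names(cmA) <- idxA
    cmB <- lapply(idxB, function(i) section_combined(recs[[pos[match(i, inc)]]]))
    names(cmB) <- idxB
    pair <- select_interblock_pair(cmA, cmB)
    fix <- recs[[pos[match(pair["i"], inc)]]]
    mov <- recs[[pos[match(pair["j"], inc)]]]
    fi <- register_pair_intensity(fix$channels, mov$channels, config)
    phi <- register_pair_mask(section_combined(fix), section_combined(mov),
                              fi, config)
    bridge <- idxB[idxB < pair["j"]]
    if (length(bridge) == 0) next
    M <- length(bridge)
    # anterior-most bridge section moves nearly fully toward the anterior
    # block; fractions decay linearly to 0 at the moving section.
    fracs <- rev(seq_len(M)) / (M + 1)
    for (m in seq_len(M)) {
      psi <- scale_field(phi, fracs[m])
      p <- pos[match(bridge[m], inc)]
      total <- compose_fields(fields[[as.character(bridge[m])]], psi)
      recs[[p]] <- warp_section(series$sections[[p]], total)
      fields[[as.character(bridge[m])]] <- total
    }
  }
  out <- series
  out$sections <- recs
  list(series = out, fields = fields, method = method,
       blocks = lapply(seq_along(blocks), function(bi)
         c(blocks[[bi]], list(reference_index = regs[[bi]]$reference_index))))
}

#' Mean Dice of combined masks on adjacent included sections
#'
#' A registration quality summary: the mean combined-mask Dice coefficient
#' over all pairs of adjacent included sections.
#'
#' @param series a `section_series`.
#' @export
adjacent_dice <- function(series) {
  inc <- included_indices(series)
  pos <- match(inc, vapply(series$sections, function(s) s$index, integer(1)))
  cm <- lapply(pos, function(p) section_combined(series$sections[[p]]))
  mean(vapply(seq_len(length(cm) - 1), function(i)
    dice(cm[[i]], cm[[i + 1]]), numeric(1)))
}
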