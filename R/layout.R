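# Axon layouts: ordered internode tables from which node positions derive.
#
# A layout is a tibble with one row per internode piece:
#   slot      original internode index (1..n_original); a remyelinated pair
#             shares its slot
#   piece     1 for a normal internode, 1:2 for the halves of a pair
#   length_um nodal separation contributed by this piece
#   g_ratio   axon/fiber diameter ratio of the sheath over this piece
#   category  "normal" or "remyelinated"
# Attributes: n_original, mask (per-slot logical), p, seed.

new_axon_layout <- function(df, n_original, mask, p = NA_real_,
                            seed = NA_integer_) {
  out <- as_tibble(df)
  attr(out, "n_original") <- as.integer(n_original)
  attr(out, "mask") <- mask
  attr(out, "p") <- p
  attr(out, "seed") <- seed
  class(out) <- c("axon_layout", class(out))
  out
}

# keep the layout class through dplyr verbs is not needed; layouts are
# constructed only by the functions below.

#' Create a uniformly myelinated axon layout
#'
#' The default geometry is the base (normal) fibre used throughout the
#' package: 120 internodes of 1150 um nodal separation (121 nodes of
#' Ranvier) with a g-ratio of 0.69.
#'
#' @param n_internodes Number of internodes (>= 1).
#' @param length_um Nodal separation of every internode, in micrometres.
#' @param g_ratio Axon-to-fibre diameter ratio, in (0, 1).
#' @return An `axon_layout` tibble; see [node_positions()],
#'   [remyelinate()], [count_transitions()].
#' @export
#' @examples
#' base <- make_uniform_layout(120, 1150, 0.69)
#' sum(base$length_um) # 138000 um
make_uniform_layout <- function(n_internodes = 120, length_um = 1150,
                                g_ratio = 0.69) {
  n <- check_count(n_internodes, "n_internodes", lower = 1L)
  check_number(length_um, "length_um", lower = 0, strict_lower = TRUE)
  check_number(g_ratio, "g_ratio", lower = 0, upper = 1, strict_lower = TRUE)
  if (g_ratio >= 1) abort("`g_ratio` must be < 1")
  df <- tibble(
    slot = seq_len(n),
    piece = 1L,
    length_um = length_um,
    g_ratio = g_ratio,
    category = "normal"
  )
  new_axon_layout(df, n, rep(FALSE, n))
}

# expand a uniform base layout according to a per-slot remyelination mask
apply_mask <- function(base, mask, remyelinated_g_ratio = NULL, p = NA_real_,
                       seed = NA_integer_) {
  n <- attr(base, "n_original")
  stopifnot(length(mask) == n)
  reps <- ifelse(mask, 2L, 1L)
  len <- base$length_um / reps
  g_new <- if (is.null(remyelinated_g_ratio)) base$g_ratio else {
    check_number(remyelinated_g_ratio, "remyelinated_g_ratio",
                 lower = 0, upper = 1, strict_lower = TRUE)
    ifelse(mask, remyelinated_g_ratio, base$g_ratio)
  }
  df <- tibble(
    slot = rep.int(seq_len(n), reps),
    piece = sequence(reps),
    length_um = rep.int(len, reps),
    g_ratio = rep.int(g_new, reps),
    category = rep.int(ifelse(mask, "remyelinated", "normal"), reps)
  )
  new_axon_layout(df, n, mask, p = p, seed = seed)
}

# draw a binomial remyelination mask under a dedicated seed
draw_mask <- function(n, p, seed) {
  if (p == 0) return(rep(FALSE, n))
  if (p == 1) return(rep(TRUE, n))
  if (is.null(seed)) {
    abort("`seed` is required when 0 < p < 1 (deterministic ensembles)")
  }
  with_seed(seed, runif(n) < p)
}

#' Randomly remyelinate a uniform axon layout
#'
#' Each original internode is independently replaced, with probability `p`,
#' by two internodes of half its nodal separation (a remyelinated pair).
#' Total axon length is conserved. Remyelinated sheaths may optionally be
#' thinner (larger g-ratio).
#'
#' @param layout A uniform (all-normal) [make_uniform_layout()] layout.
#' @param p Remyelination fraction in \[0, 1\].
#' @param seed Integer seed; required for 0 < p < 1. The draw is
#'   deterministic for a fixed seed and does not touch the global RNG state.
#' @param remyelinated_g_ratio Optional g-ratio for remyelinated pieces
#'   (e.g. 0.86 for thin remyelinated sheaths); default keeps the original.
#' @return An `axon_layout` with the remyelination mask recorded in
#'   `attr(, "mask")`.
#' @export
#' @examples
#' base <- make_uniform_layout(120, 1150, 0.69)
#' rem <- remyelinate(base, p = 0.5, seed = 1)
#' sum(attr(rem, "mask"))
remyelinate <- function(layout, p, seed = NULL, remyelinated_g_ratio = NULL) {
  stopifnot(inherits(layout, "axon_layout"))
  check_number(p, "p", lower = 0, upper = 1)
  if (any(layout$category != "normal")) {
    abort("`layout` must be uniform (all internodes normal) before remyelination")
  }
  n <- attr(layout, "n_original")
  mask <- draw_mask(n, p, seed)
  apply_mask(layout, mask, remyelinated_g_ratio, p = p,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Remyelinate with an exact count inside chosen slots
#'
#' Conditional variant of [remyelinate()]: exactly `k` of the internodes in
#' `slots` are remyelinated (uniformly at random over compositions, i.e. the
#' binomial distribution conditioned on its count), while internodes outside
#' `slots` are remyelinated independently with probability `p_outside`.
#' Used for fixed-composition analyses of the transition-count effect.
#'
#' @inheritParams remyelinate
#' @param k Exact number of remyelinated internodes within `slots`.
#' @param slots Integer vector of original-internode indices the count
#'   applies to; default all slots.
#' @param p_outside Remyelination probability outside `slots`.
#' @return An `axon_layout`.
#' @export
remyelinate_exact <- function(layout, k, slots = NULL, p_outside = 0,
                              seed = NULL, remyelinated_g_ratio = NULL) {
  stopifnot(inherits(layout, "axon_layout"))
  if (any(layout$category != "normal")) {
    abort("`layout` must be uniform (all internodes normal) before remyelination")
  }
  n <- attr(layout, "n_original")
  slots <- slots %||% seq_len(n)
  stopifnot(all(slots >= 1), all(slots <= n), !anyDuplicated(slots))
  k <- check_count(k, "k")
  if (k > length(slots)) abort("`k` cannot exceed the number of slots")
  check_number(p_outside, "p_outside", lower = 0, upper = 1)
  if (is.null(seed)) abort("`seed` is required")
  mask <- with_seed(seed, {
    m <- rep(FALSE, n)
    if (k > 0) m[sample(slots, k)] <- TRUE
    outside <- setdiff(seq_len(n), slots)
    if (length(outside) > 0 && p_outside > 0) {
      m[outside] <- runif(length(outside)) < p_outside
    }
    m
  })
  apply_mask(layout, mask, remyelinated_g_ratio, p = NA_real_,
             seed = as.integer(seed))
}

#' Create a semi-uniform axon layout
#'
#' A contiguous block of full-length internodes next to a contiguous block
#' of remyelinated (half-length) pairs, with exactly one transition node
#' between the two regions.
#'
#' @param n_long Number of full-length internodes (>= 1).
#' @param n_short_pairs Number of remyelinated pairs (>= 1); each pair
#'   occupies one original-internode slot and contributes two half-length
#'   internodes.
#' @param orientation `"long_first"` puts the long block proximal (the
#'   action potential meets a long-to-short transition), `"short_first"`
#'   the reverse.
#' @inheritParams make_uniform_layout
#' @param remyelinated_g_ratio Optional g-ratio for the remyelinated block.
#' @return An `axon_layout`.
#' @export
#' @examples
#' semi <- make_semi_uniform(35, 35, "long_first")
#' count_transitions(semi)
make_semi_uniform <- function(n_long, n_short_pairs,
                              orientation = c("long_first", "short_first"),
                              length_um = 1150, g_ratio = 0.69,
                              remyelinated_g_ratio = NULL) {
  n_long <- check_count(n_long, "n_long", lower = 1L)
  n_short_pairs <- check_count(n_short_pairs, "n_short_pairs", lower = 1L)
  orientation <- match.arg(orientation)
  base <- make_uniform_layout(n_long + n_short_pairs, length_um, g_ratio)
  mask <- if (orientation == "long_first") {
    c(rep(FALSE, n_long), rep(TRUE, n_short_pairs))
  } else {
    c(rep(TRUE, n_short_pairs), rep(FALSE, n_long))
  }
  apply_mask(base, mask, remyelinated_g_ratio)
}

#' Node positions along a layout
#'
#' @param layout An `axon_layout`.
#' @return Numeric vector of node positions in micrometres, starting at 0;
#'   length is one more than the number of internode pieces.
#' @export
node_positions <- function(layout) {
  stopifnot(inherits(layout, "axon_layout"))
  c(0, cumsum(layout$length_um))
}

#' Define stimulating and recording electrode positions
#'
#' Electrodes are fixed at physical positions (micrometres from the
#' proximal end) so that the same measurement span is used for every
#' remyelinated realisation of the same base axon. The defaults place the
#' stimulus at 11500 um (node 11 of the base 120-internode axon, avoiding
#' the sealed proximal end) and the recording pair at 34500 and 115000 um
#' (base nodes 31 and 101), a separation of 80500 um.
#'
#' @param stim_um Stimulation position in micrometres.
#' @param rec_um Two recording positions in micrometres, strictly
#'   increasing and distal to `stim_um`.
#' @return An `electrode_set` object.
#' @export
electrode_set <- function(stim_um = 11500, rec_um = c(34500, 115000)) {
  check_number(stim_um, "stim_um", lower = 0)
  if (length(rec_um) != 2L || !is.numeric(rec_um)) {
    abort("`rec_um` must be two recording positions")
  }
  if (!(rec_um[1] > stim_um && rec_um[2] > rec_um[1])) {
    abort("recording positions must be strictly ordered and distal to the stimulus")
  }
  structure(list(stim_um = stim_um, rec_um = as.numeric(rec_um)),
            class = "electrode_set")
}

#' @rdname electrode_set
#' @export
default_electrodes <- function() electrode_set()

#' Resolve electrode positions to node indices of a layout
#'
#' Maps each physical electrode position to the index (1-based) of the
#' node at that position. Positions that fall between nodes are assigned
#' to the nearest node, with ties broken towards the proximal end; for the
#' default halving geometry every base-node position coincides exactly
#' with a node of any remyelinated layout.
#'
#' @param layout An `axon_layout`.
#' @param electrodes An [electrode_set()].
#' @return A tibble with columns `role` ("stim", "rec1", "rec2"),
#'   `target_um`, `node` (1-based node index) and `node_um` (the resolved
#'   node's position).
#' @export
#' @examples
#' base <- make_uniform_layout(120, 1150, 0.69)
#' resolve_electrodes(base, default_electrodes()) # nodes 11, 31, 101
resolve_electrodes <- function(layout, electrodes = default_electrodes()) {
  stopifnot(inherits(layout, "axon_layout"),
            inherits(electrodes, "electrode_set"))
  pos <- node_positions(layout)
  total <- pos[length(pos)]
  targets <- c(stim = electrodes$stim_um,
               rec1 = electrodes$rec_um[1],
               rec2 = electrodes$rec_um[2])
  tol <- 1e-6 * max(1, total)
  idx <- vapply(targets, function(x) {
    if (x < -tol || x > total + tol) {
      abort(sprintf("electrode position %g um lies beyond the axon end (%g um)",
                    x, total))
    }
    d <- abs(pos - x)
    which(d <= min(d) + tol)[1] # ties resolve to the proximal node
  }, integer(1))
  tibble(role = names(targets), target_um = unname(targets),
         node = unname(idx), node_um = pos[idx])
}

#' Count transitions between long and short internode regions
#'
#' Classifies each original internode slot (a remyelinated pair counts as
#' one short slot) and counts category changes between adjacent slots in
#' the proximal-to-distal direction.
#'
#' @param layout An `axon_layout`.
#' @param slots Optional integer vector restricting the count to a
#'   contiguous range of original-slot indices (e.g. the measurement span).
#' @return A one-row tibble with `n_long_to_short` and `n_short_to_long`.
#' @export
count_transitions <- function(layout, slots = NULL) {
  stopifnot(inherits(layout, "axon_layout"))
  mask <- attr(layout, "mask") # TRUE = short (remyelinated) slot
  if (!is.null(slots)) mask <- mask[slots]
  a <- mask[-length(mask)]
  b <- mask[-1]
  tibble(
    n_long_to_short = sum(!a & b),
    n_short_to_long = sum(a & !b)
  )
}

#' Binomial spread of the remyelinated-segment count
#'
#' Standard deviation `sqrt(N p (1 - p))` of the number of remyelinated
#' segments among `N` internodes at remyelination fraction `p`.
#'
#' @param N Number of internodes subject to remyelination.
#' @param p Remyelination fraction.
#' @return Numeric (vectorised over `N` and `p`).
#' @export
#' @examples
#' binomial_sigma(70, 0.5) # about 4.2
binomial_sigma <- function(N, p) {
  stopifnot(all(N >= 0), all(p >= 0 & p <= 1))
  sqrt(N * p * (1 - p))
}

#' Average internode length of a remyelinated axon
#'
#' Total length divided by the expected internode count: an axon whose
#' normal nodal separation is `length_um` has, at remyelination fraction
#' `p`, on average `(1 + p)` internodes per original slot, so the average
#' separation is `length_um / (1 + p)`.
#'
#' @param length_um Normal nodal separation in micrometres.
#' @param p Remyelination fraction.
#' @return Average nodal separation in micrometres (vectorised).
#' @export
average_internode_length <- function(length_um, p) {
  stopifnot(all(length_um > 0), all(p >= 0 & p <= 1))
  length_um / (1 + p)
}

#' Generate an ensemble of remyelinated axon layouts
#'
#' Draws `n_models` independently remyelinated copies of the base axon.
#' Draw `i` uses the counter-based [child_seed()] of `(master_seed, i)`, so
#' regeneration with the same arguments is bit-identical and draws are
#' independent of evaluation order.
#'
#' @param p Remyelination fraction.
#' @param n_models Number of draws (paper protocol: 500 per `p`).
#' @param master_seed Integer master seed.
#' @inheritParams make_uniform_layout
#' @param remyelinated_g_ratio Optional g-ratio for remyelinated pieces.
#' @param keep_layouts If `FALSE`, only the per-draw seeds, masks and
#'   remyelinated counts are returned (fast path for combinatorial checks).
#' @return A tibble with columns `draw`, `seed`, `n_remyelinated` and (if
#'   `keep_layouts`) a `layout` list-column.
#' @export
axon_ensemble <- function(p, n_models = 500, master_seed = 1,
                          n_internodes = 120, length_um = 1150,
                          g_ratio = 0.69, remyelinated_g_ratio = NULL,
                          keep_layouts = TRUE) {
  check_number(p, "p", lower = 0, upper = 1)
  n_models <- check_count(n_models, "n_models", lower = 1L)
  base <- make_uniform_layout(n_internodes, length_um, g_ratio)
  n <- attr(base, "n_original")
  seeds <- child_seed(master_seed, seq_len(n_models))
  masks <- purrr::map(seeds, function(s) draw_mask(n, p, s))
  out <- tibble(
    draw = seq_len(n_models),
    seed = seeds,
    n_remyelinated = purrr::map_int(masks, ~ sum(.x))
  )
  if (keep_layouts) {
    out$layout <- purrr::map2(masks, seeds, function(m, s) {
      apply_mask(base, m, remyelinated_g_ratio, p = p, seed = s)
    })
  }
  out
}

#' Write / read an axon layout as flat CSV
#'
#' The header carries the seed and remyelination fraction as `#`-prefixed
#' comment lines; the table round-trips bit-exactly.
#'
#' @param layout An `axon_layout`.
#' @param path File path.
#' @return `write_axon_layout()` returns `path` invisibly;
#'   `read_axon_layout()` returns the layout.
#' @export
write_axon_layout <- function(layout, path) {
  stopifnot(inherits(layout, "axon_layout"))
  header <- c(
    sprintf("# n_original: %d", attr(layout, "n_original")),
    sprintf("# p: %s", format(attr(layout, "p"), digits = 17)),
    sprintf("# seed: %s", format(attr(layout, "seed")))
  )
  body <- readr::format_csv(as_tibble(layout))
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_axon_layout
#' @export
read_axon_layout <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), comments, value = TRUE)
    if (length(ln) == 0) return(NA)
    trimws(sub(sprintf("^# %s:", key), "", ln[1]))
  }
  df <- readr::read_csv(I(paste(grep("^#", lines, value = TRUE, invert = TRUE),
                                collapse = "\n")),
                        col_types = readr::cols(
                          slot = "i", piece = "i", length_um = "d",
                          g_ratio = "d", category = "c"
                        ))
  n_original <- as.integer(get_field("n_original"))
  mask <- vapply(split(df$category, df$slot),
                 function(x) x[1] == "remyelinated", logical(1))
  p <- suppressWarnings(as.numeric(get_field("p")))
  seed <- suppressWarnings(as.integer(get_field("seed")))
  new_axon_layout(df, n_original, unname(mask[order(as.integer(names(mask)))]),
                  p = p, seed = if (is.na(seed)) NA_integer_ else seed)
}
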