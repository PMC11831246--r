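# Posner-style dot-pattern stimulus generation.
#
# A pattern is 9 dots on a planar canvas. The prototype is drawn on integer
# grid points in the central region of the canvas; category members are
# radial distortions of the prototype at distortion levels (DL) 4-7;
# nonmembers are unrelated random patterns. Distances between patterns are
# Euclidean norms in the 18-dimensional stacked-coordinate space.

#' Default per-level distortion magnitudes
#'
#' Maximum radial displacement (grid units) applied per dot at each
#' distortion level. Displacement radii are drawn uniformly on
#' `[0, magnitude]`, so expected displacement grows strictly with level.
#' The level-to-magnitude mapping is a configurable convention, calibrated
#' so that members fall within the default member distance constraint with
#' high acceptance.
#'
#' @return Named numeric vector over levels `"4"`-`"7"`.
#' @export
default_distortion_magnitudes <- function() {
  c("4" = 1.5, "5" = 2.1, "6" = 2.7, "7" = 3.3)
}

new_dot_pattern <- function(id, role, dots, dl = NA_integer_) {
  stopifnot(is.matrix(dots), nrow(dots) == 9L, ncol(dots) == 2L)
  structure(
    list(id = as.character(id), role = role,
         distortion_level = if (is.na(dl)) NA_integer_ else as.integer(dl),
         dots = unname(dots)),
    class = "dot_pattern"
  )
}

#' @export
print.dot_pattern <- function(x, ...) {
  lvl <- if (is.na(x$distortion_level)) "" else paste0(" DL", x$distortion_level)
  cat(sprintf("<dot_pattern %s: %s%s, 9 dots>\n", x$id, x$role, lvl))
  invisible(x)
}

validate_canvas <- function(canvas) {
  if (!is.numeric(canvas) || length(canvas) != 2L || any(canvas < 30))
    stop("canvas must be at least 30x30 grid units", call. = FALSE)
  canvas
}

# Integer grid points of the central region (a 30x30 window centred on the
# canvas), as an m x 2 matrix.
central_grid <- function(canvas) {
  off <- floor((canvas - 30) / 2)
  xs <- seq.int(off[1] + 1L, off[1] + 30L)
  ys <- seq.int(off[2] + 1L, off[2] + 30L)
  as.matrix(expand.grid(x = xs, y = ys))
}

# Draw 9 distinct grid points from the central region using the current
# RNG stream.
draw_random_pattern <- function(canvas) {
  grid <- central_grid(canvas)
  idx <- sample.int(nrow(grid), 9L, replace = FALSE)
  unname(grid[idx, , drop = FALSE]) * 1.0
}

#' Generate a 9-dot prototype pattern
#'
#' Places 9 distinct dots uniformly on integer grid points within the
#' central 30x30 region of the canvas. Deterministic given `rng_seed`.
#'
#' @param rng_seed Integer seed, or `NULL` to use the current RNG stream.
#' @param canvas Canvas extent `c(width, height)` in grid units; at least
#'   30x30.
#' @param id Pattern identifier.
#' @return A `dot_pattern` with role `"prototype"`.
#' @export
generate_prototype <- function(rng_seed = NULL, canvas = c(50, 50),
                               id = "proto") {
  validate_canvas(canvas)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  new_dot_pattern(id, "prototype", draw_random_pattern(canvas))
}

#' Distort a prototype into a category member
#'
#' Each dot is displaced independently by a radial jitter: direction
#' uniform on the circle, radius uniform on `[0, magnitude[level]]`. Dot
#' order (index correspondence to the prototype) is preserved, so
#' prototype-relative distances need no assignment solving.
#'
#' @param proto A `dot_pattern` (typically the prototype).
#' @param level Distortion level, one of 4, 5, 6, 7.
#' @param rng_seed Integer seed, or `NULL` for the current stream.
#' @param magnitudes Named vector of per-level maximum displacement radii;
#'   see [default_distortion_magnitudes()].
#' @param canvas Canvas bounds the distorted dots must stay within.
#' @param id Identifier for the distorted pattern.
#' @return A `dot_pattern` with role `"member"` and the given level.
#' @export
distort_pattern <- function(proto, level, rng_seed = NULL,
                            magnitudes = default_distortion_magnitudes(),
                            canvas = c(50, 50), id = NULL) {
  if (!level %in% c(4L, 5L, 6L, 7L))
    stop("distortion level must be one of 4, 5, 6, 7", call. = FALSE)
  validate_canvas(canvas)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  mag <- magnitudes[[as.character(level)]]
  if (is.null(mag) || mag < 0)
    stop("no displacement magnitude configured for level ", level,
         call. = FALSE)
  dots <- proto$dots
  for (attempt in 1:100) {
    theta <- stats::runif(9L, 0, 2 * pi)
    radius <- stats::runif(9L, 0, mag)
    cand <- proto$dots + cbind(radius * cos(theta), radius * sin(theta))
    inside <- all(cand[, 1] >= 0 & cand[, 1] <= canvas[1] &
                  cand[, 2] >= 0 & cand[, 2] <= canvas[2])
    if (inside) { dots <- cand; break }
    if (attempt == 100)
      stop("could not place distorted dots inside the canvas", call. = FALSE)
  }
  if (is.null(id)) id <- paste0(proto$id, "_dl", level)
  new_dot_pattern(id, "member", dots, dl = level)
}

#' Euclidean distance between two dot patterns
#'
#' Distance in the 18-dimensional stacked-coordinate space,
#' `sqrt(sum over dots of (dx^2 + dy^2))`, with dots matched by index.
#'
#' @param a,b `dot_pattern` objects with 9 dots each.
#' @return Non-negative scalar distance in grid units.
#' @export
pattern_distance <- function(a, b) {
  da <- if (inherits(a, "dot_pattern")) a$dots else a
  db <- if (inherits(b, "dot_pattern")) b$dots else b
  if (!identical(dim(da), dim(db)))
    stop("patterns must have matching dot counts", call. = FALSE)
  sqrt(sum((da - db)^2))
}

# Rejection-sample one item until a prototype-distance predicate holds.
sample_with_constraint <- function(make, accept, max_attempts, what) {
  for (i in seq_len(max_attempts)) {
    cand <- make()
    if (accept(cand)) return(list(pattern = cand, attempts = i))
  }
  stop(sprintf(
    "rejection sampling exceeded %d attempts while enforcing the %s constraint",
    max_attempts, what), call. = FALSE)
}

#' Build the full 41-pattern stimulus inventory
#'
#' Assembles one prototype, 12 training members (4 each at DL5, DL6, DL7),
#' 12 training nonmembers, 8 novel members (2 each at DL4-DL7) and 8 novel
#' nonmembers. Members are rejection-sampled until their distance to the
#' prototype is at most `member_dmax`; nonmembers until at least
#' `nonmember_dmin`. The transfer set is the prototype plus the 24 training
#' items plus the 16 novel items (41 items); the prototype is withheld
#' during training.
#'
#' @param rng_seed Integer seed; the whole set is reproducible from it.
#' @param canvas Canvas extent, default 50x50 grid units.
#' @param member_dmax Maximum member-to-prototype distance (default 6.22).
#' @param nonmember_dmin Minimum nonmember-to-prototype distance
#'   (default 12.93).
#' @param magnitudes Distortion magnitude table, see
#'   [default_distortion_magnitudes()].
#' @param max_attempts Rejection-sampling cap per item; exceeding it is an
#'   error, never a silent relaxation.
#' @return A `stimulus_set`.
#' @export
build_stimulus_set <- function(rng_seed, canvas = c(50, 50),
                               member_dmax = 6.22, nonmember_dmin = 12.93,
                               magnitudes = default_distortion_magnitudes(),
                               max_attempts = 10000L) {
  validate_canvas(canvas)
  if (member_dmax >= nonmember_dmin)
    stop("member_dmax must be smaller than nonmember_dmin", call. = FALSE)
  set.seed(rng_seed)
  proto <- generate_prototype(rng_seed = NULL, canvas = canvas)

  attempts <- c(member = 0, nonmember = 0)
  make_member <- function(id, level) {
    res <- sample_with_constraint(
      make = function() distort_pattern(proto, level, rng_seed = NULL,
                                        magnitudes = magnitudes,
                                        canvas = canvas, id = id),
      accept = function(p) pattern_distance(p, proto) <= member_dmax,
      max_attempts = max_attempts, what = "member-distance")
    attempts["member"] <<- attempts["member"] + res$attempts
    res$pattern
  }
  make_nonmember <- function(id) {
    res <- sample_with_constraint(
      make = function() new_dot_pattern(id, "nonmember",
                                        draw_random_pattern(canvas)),
      accept = function(p) pattern_distance(p, proto) >= nonmember_dmin,
      max_attempts = max_attempts, what = "nonmember-distance")
    attempts["nonmember"] <<- attempts["nonmember"] + res$attempts
    res$pattern
  }

  train_dls <- rep(c(5L, 6L, 7L), each = 4L)
  training_members <- lapply(seq_along(train_dls), function(i)
    make_member(sprintf("tm%02d_dl%d", i, train_dls[i]), train_dls[i]))
  training_nonmembers <- lapply(1:12, function(i)
    make_nonmember(sprintf("tn%02d", i)))
  novel_dls <- rep(c(4L, 5L, 6L, 7L), times = 2L)
  novel_members <- lapply(seq_along(novel_dls), function(i)
    make_member(sprintf("nm%02d_dl%d", i, novel_dls[i]), novel_dls[i]))
  novel_nonmembers <- lapply(1:8, function(i)
    make_nonmember(sprintf("nn%02d", i)))

  structure(
    list(prototype = proto,
         training_members = training_members,
         training_nonmembers = training_nonmembers,
         novel_members = novel_members,
         novel_nonmembers = novel_nonmembers,
         canvas = canvas, seed = as.integer(rng_seed),
         config = list(member_dmax = member_dmax,
                       nonmember_dmin = nonmember_dmin,
                       magnitudes = magnitudes),
         acceptance = list(
           member_rate = 24 / attempts[["member"]],
           nonmember_rate = 20 / attempts[["nonmember"]])),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<stimulus_set seed=%d: prototype + %d/%d training members/nonmembers",
    " + %d/%d novel members/nonmembers>\n"),
    x$seed, length(x$training_members), length(x$training_nonmembers),
    length(x$novel_members), length(x$novel_nonmembers)))
  invisible(x)
}

#' All patterns of a stimulus set
#'
#' @param set A `stimulus_set`.
#' @param phase `"all"` (full 41-item inventory, also the transfer set) or
#'   `"training"` (the 24 training items; the prototype is withheld).
#' @return Named list of `dot_pattern`s.
#' @export
stimulus_patterns <- function(set, phase = c("all", "training")) {
  phase <- match.arg(phase)
  pats <- if (phase == "training") {
    c(set$training_members, set$training_nonmembers)
  } else {
    c(list(set$prototype), set$training_members, set$training_nonmembers,
      set$novel_members, set$novel_nonmembers)
  }
  stats::setNames(pats, vapply(pats, `[[`, character(1), "id"))
}

#' Pairwise distance table over a stimulus set
#'
#' @param set A `stimulus_set`.
#' @param phase Passed to [stimulus_patterns()].
#' @return Symmetric matrix of 18-D Euclidean distances with pattern ids as
#'   dimnames.
#' @export
distance_table <- function(set, phase = "all") {
  pats <- stimulus_patterns(set, phase)
  coords <- t(vapply(pats, function(p) as.numeric(p$dots), numeric(18)))
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(names(pats), names(pats))
  d
}

#' Write a stimulus set to JSON
#'
#' Schema: `{"seed": int, "canvas": [w,h], "patterns": [{"id", "role",
#' "dl", "dots": [[x,y] x 9]}]}`. Coordinates round-trip bit-exactly
#' through [read_stimuli()].
#'
#' @param set A `stimulus_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(set, path) {
  pats <- stimulus_patterns(set, "all")
  obj <- list(
    seed = set$seed,
    canvas = set$canvas,
    config = set$config[c("member_dmax", "nonmember_dmin")],
    patterns = lapply(unname(pats), function(p) list(
      id = p$id, role = p$role,
      dl = if (is.na(p$distortion_level)) NULL else p$distortion_level,
      dots = apply(p$dots, 1, identity, simplify = FALSE)))
  )
  # 17 significant digits round-trip IEEE doubles exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a stimulus set from JSON
#'
#' Inverse of [write_stimuli()]; reconstructs the `stimulus_set` partition
#' from the id prefixes and roles.
#'
#' @param path JSON file written by [write_stimuli()].
#' @return A `stimulus_set`.
#' @export
read_stimuli <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed stimulus file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(obj$patterns))
    stop("malformed stimulus file '", path, "': no patterns record",
         call. = FALSE)
  pats <- lapply(obj$patterns, function(p) {
    if (length(p$dots) != 9L)
      stop("malformed stimulus file: pattern '", p$id, "' has ",
           length(p$dots), " dot rows, expected 9", call. = FALSE)
    dots <- do.call(rbind, lapply(p$dots, as.numeric))
    # a JSON null round-trips as an empty element, not NULL
    dl <- if (length(p$dl) == 0) NA_integer_ else as.integer(p$dl)
    new_dot_pattern(p$id, p$role, dots, dl = dl)
  })
  roles <- vapply(pats, `[[`, character(1), "role")
  ids <- vapply(pats, `[[`, character(1), "id")
  pick <- function(prefix) pats[startsWith(ids, prefix)]
  structure(
    list(prototype = pats[roles == "prototype"][[1]],
         training_members = pick("tm"),
         training_nonmembers = pick("tn"),
         novel_members = pick("nm"),
         novel_nonmembers = pick("nn"),
         canvas = as.numeric(unlist(obj$canvas)),
         seed = as.integer(obj$seed),
         config = lapply(obj$config, as.numeric),
         acceptance = NULL),
    class = "stimulus_set"
  )
}

#' Tabulate a stimulus set as one row per dot
#'
#' @param set A `stimulus_set`.
#' @return Data frame with columns `pattern_id`, `role`, `dl`,
#'   `dot_index`, `x`, `y` (41 patterns x 9 dots = 369 rows for the full
#'   inventory), suitable for CSV export and plotting.
#' @export
stimuli_to_df <- function(set) {
  pats <- stimulus_patterns(set, "all")
  do.call(rbind, lapply(unname(pats), function(p) data.frame(
    pattern_id = p$id, role = p$role, dl = p$distortion_level,
    dot_index = 1:9, x = p$dots[, 1], y = p$dots[, 2])))
}
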