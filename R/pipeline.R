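#' Default pipeline parameters
#'
#' One place for every tunable of the quantification pipeline; any entry
#' can be overridden per run via the config. Values are the package's
#' defaults (reconstructions where the underlying workflow left them
#' unstated), all in physical units.
#'
#' @return nested list of parameters.
#' @export
default_params <- function() {
  list(
    median_radius = 1L,
    villi = list(method = "otsu", min_size_um3 = 500, fill_holes = TRUE),
    vessels = list(method = "otsu", min_size_um3 = 200, fill_holes = FALSE),
    nuclei = list(sigma_range = c(1.2, 1.8), min_distance = 2,
                  threshold_rel = 0.1, n_scales = 3L),
    knots = list(eps = 9, min_pts = 3L, min_members = 10L,
                 intensity_gate = 1.3),
    network = list(prune_spur_factor = 1, include_terminal = FALSE)
  )
}

merge_params <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Quantify one image: masks to the eight canonical metrics
#'
#' The per-image core of the pipeline: given a stack (segmented internally)
#' or externally supplied masks/labels, computes villous volume, surface
#' area, SA/Vol, nuclear density, knot fraction, vascular fraction,
#' branchpoint density and mean tortuosity.
#'
#' @param stack an [image_stack()] with channels `villi`, `nuclei`,
#'   `vessels`, or NULL when all masks are supplied externally.
#' @param masks optional list with any of `villi` ([binary_mask()]),
#'   `vessels` ([binary_mask()]), `nuclei` ([label_map()]) to bypass the
#'   corresponding segmentation stage.
#' @param params parameter list, see [default_params()].
#' @return list with `metrics` (one-row tibble) and `details` (records,
#'   knots, graph).
#' @export
quantify_image <- function(stack = NULL, masks = list(),
                           params = default_params()) {
  if (is.null(stack) &&
      (is.null(masks$villi) || is.null(masks$vessels) || is.null(masks$nuclei))) {
    abort("without a stack, villi + vessels masks and nuclei labels are required")
  }
  den <- NULL
  if (!is.null(stack) && (is.null(masks$villi) || is.null(masks$vessels))) {
    den <- denoise_median(stack, params$median_radius)
  }
  villi <- masks$villi %||% segment_channel(
    den, "villi", method = params$villi$method,
    min_size_um3 = params$villi$min_size_um3,
    fill_holes = params$villi$fill_holes
  )
  vessels <- masks$vessels %||% segment_channel(
    den, "vessels", method = params$vessels$method,
    min_size_um3 = params$vessels$min_size_um3,
    fill_holes = params$vessels$fill_holes
  )
  # blob detection carries its own scale-space smoothing; the median
  # prefilter would smear the intensity dips between touching nuclei
  # (especially along the coarse z axis), so instances are segmented on
  # the raw channel
  nuclei <- masks$nuclei %||% segment_nuclei_instances(
    stack, "nuclei", sigma_range = params$nuclei$sigma_range,
    min_distance = params$nuclei$min_distance,
    threshold_rel = params$nuclei$threshold_rel,
    n_scales = params$nuclei$n_scales
  )
  records <- extract_nucleus_records(
    nuclei, stack = stack,
    channel = if (is.null(stack)) NULL else "nuclei"
  )
  vol <- mask_volume(villi)
  area <- mesh_surface_area(villi)
  knots <- detect_knots(records, nuclei, eps = params$knots$eps,
                        min_pts = params$knots$min_pts,
                        min_members = params$knots$min_members,
                        intensity_gate = params$knots$intensity_gate)
  vessel_in <- binary_mask(vessels$data & villi$data, vessels$spacing)
  graph <- if (any(vessel_in$data)) {
    build_network(skeletonize(vessel_in),
                  prune_spur_factor = params$network$prune_spur_factor)
  } else {
    NULL
  }
  mt <- if (!is.null(graph)) {
    mean_tortuosity(graph, include_terminal = params$network$include_terminal)
  } else {
    list(mean_tortuosity = NA_real_)
  }
  metrics <- tibble(
    villous_volume_um3 = vol,
    surface_area_um2 = area,
    sa_vol_per_um = area / vol,
    nuclear_density_per_mm3 = nuclear_density(records, villi),
    knot_fraction_pct = knot_fraction(knots, vol),
    vascular_fraction_pct = vascular_fraction(vessels, villi),
    branchpoint_density_per_um = if (!is.null(graph) &&
                                     sum(graph$edges$arc_length_um) > 0) {
      branchpoint_density(graph)
    } else {
      NA_real_
    },
    mean_tortuosity = mt$mean_tortuosity
  )
  list(metrics = metrics,
       details = list(records = records, knots = knots, graph = graph,
                      villi = villi, vessels = vessels, nuclei = nuclei))
}

#' Load a run configuration
#'
#' Configs are YAML (or an equivalent R list): a mandatory `seed`, an
#' `images` list (each with `id`, `group`, and either `phantom:` with a
#' preset/overrides or `files:` with paths to a stack and/or external
#' masks), and an optional `params` block overriding [default_params()].
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must carry a seed")
  if (!length(config$images)) abort("config lists no images")
  for (im in config$images) {
    if (is.null(im$id)) abort("every image entry needs an id")
    if (is.null(im$phantom) && is.null(im$files)) {
      abort(sprintf("image '%s' has neither a phantom nor files", im$id))
    }
  }
  config$params <- merge_params(default_params(), config$params)
  config
}

#' Run the full quantification pipeline
#'
#' For each configured image: generate the phantom (or load external
#' data), denoise, segment villi/vessels/nuclei (or use supplied masks),
#' and compute all morphometry, knot and network metrics — one report row
#' per image. A failing image is reported in an `error` column and the
#' remaining images still run. Fully reproducible for a fixed config +
#' seed (per-image seeds are derived from the config seed).
#'
#' @param config path to a YAML config or a config list (see
#'   [load_config()]).
#' @return a `morphometry_report` tibble: `image_id`, `group`, the eight
#'   metric columns, and `error`; the parameter log is attached as the
#'   `params` attribute.
#' @export
run_quantification <- function(config) {
  config <- load_config(config)
  params <- config$params
  rows <- list()
  for (i in seq_along(config$images)) {
    im <- config$images[[i]]
    seed_i <- as.integer(config$seed) + 1000L * i
    row <- tryCatch({
      inputs <- resolve_image_inputs(im, seed_i)
      q <- quantify_image(stack = inputs$stack, masks = inputs$masks,
                          params = params)
      dplyr::bind_cols(
        tibble(image_id = im$id, group = im$group %||% NA_character_),
        q$metrics, tibble(error = NA_character_)
      )
    }, error = function(e) {
      dplyr::bind_cols(
        tibble(image_id = im$id, group = im$group %||% NA_character_),
        tibble(!!!setNames(rep(list(NA_real_), 8), report_metric_columns())),
        tibble(error = conditionMessage(e))
      )
    })
    rows[[i]] <- row
  }
  report <- bind_rows(rows)
  attr(report, "params") <- params
  attr(report, "seed") <- config$seed
  class(report) <- c("morphometry_report", class(report))
  report
}

resolve_image_inputs <- function(im, seed) {
  if (!is.null(im$phantom)) {
    spec <- if (identical(im$phantom$preset %||% "demo", "demo")) {
      demo_phantom_spec()
    } else {
      abort(sprintf("unknown phantom preset '%s'", im$phantom$preset))
    }
    ph <- generate_phantom(spec, seed)
    masks <- list()
    if (isTRUE(im$phantom$use_truth_masks)) {
      masks <- list(villi = ph$truth$villous_mask,
                    vessels = ph$truth$vessel_mask,
                    nuclei = ph$truth$nuclei_labels)
    }
    return(list(stack = ph$stack, masks = masks))
  }
  f <- im$files
  masks <- list()
  stack <- NULL
  if (!is.null(f$stack)) {
    ov <- if (!is.null(f$spacing)) do.call(voxel_spacing, as.list(f$spacing))
    stack <- read_stack(f$stack, spacing_override = ov)
  }
  if (!is.null(f$villi_mask)) masks$villi <- read_mask_nrrd(f$villi_mask)
  if (!is.null(f$vessel_mask)) masks$vessels <- read_mask_nrrd(f$vessel_mask)
  if (!is.null(f$nuclei_labels)) masks$nuclei <- read_label_map(f$nuclei_labels)
  list(stack = stack, masks = masks)
}

#' Compare a metric across groups
#'
#' Group comparison as used for the imaging metrics: one-way ANOVA with a
#' Bonferroni-adjusted pairwise post-test for (assumed) normal data, or
#' Kruskal-Wallis with Dunn's post-test otherwise; `method = "auto"`
#' chooses by Shapiro-Wilk normality (attempted per group when n >= 3;
#' with smaller groups normality is assumed, with a logged caveat). Groups
#' with a single value are reported but excluded from testing.
#'
#' @param data a data frame with a metric column and a group column
#'   (default `value`, `group`).
#' @param value,group column names.
#' @param method `"anova_bonferroni"`, `"kruskal_dunn"` or `"auto"`.
#' @param alpha significance level for flags (default 0.05).
#' @return a `group_comparison` object: `omnibus` and `pairwise` tibbles,
#'   excluded groups and notes; see also [tidy()] and [glance()].
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           method = c("anova_bonferroni", "kruskal_dunn",
                                      "auto"),
                           alpha = 0.05) {
  method <- match.arg(method)
  v <- data[[value]]
  g <- as.character(data[[group]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  counts <- table(g)
  if (length(counts) < 2) abort("need at least two groups")
  excluded <- tibble(group = names(counts)[counts < 2],
                     n = as.integer(counts[counts < 2]))
  keep <- g %in% names(counts)[counts >= 2]
  notes <- character(0)
  if (nrow(excluded) > 0) {
    notes <- c(notes, sprintf(
      "group(s) with a single value reported but not tested: %s",
      paste(excluded$group, collapse = ", ")
    ))
  }
  v2 <- v[keep]; g2 <- factor(g[keep])
  if (nlevels(g2) < 2) {
    return(new_group_comparison(
      omnibus = tibble(method = method, statistic = NA_real_,
                       df = NA_real_, p_value = NA_real_),
      pairwise = tibble(group1 = character(0), group2 = character(0),
                        p_adj = numeric(0), significant = logical(0)),
      excluded = excluded, alpha = alpha,
      notes = c(notes, "fewer than two testable groups; no test performed")
    ))
  }
  if (method == "auto") {
    ns <- table(g2)
    if (any(ns < 3)) {
      notes <- c(notes, "groups with n < 3: normality not assessable, assumed (parametric path)")
      method <- "anova_bonferroni"
    } else {
      sw <- vapply(levels(g2), function(l) {
        x <- v2[g2 == l]
        if (length(unique(x)) < 3) return(NA_real_)
        stats::shapiro.test(x)$p.value
      }, numeric(1))
      method <- if (any(sw < 0.05, na.rm = TRUE)) "kruskal_dunn" else "anova_bonferroni"
      notes <- c(notes, sprintf("auto-selected %s by Shapiro-Wilk", method))
    }
  }
  if (stats::var(v2) < .Machine$double.eps) {
    # identical constant groups: no differences to find
    lv <- levels(g2)
    pr <- t(utils::combn(lv, 2))
    return(new_group_comparison(
      omnibus = tibble(method = method, statistic = 0, df = NA_real_,
                       p_value = 1),
      pairwise = tibble(group1 = pr[, 1], group2 = pr[, 2], p_adj = 1,
                        significant = FALSE),
      excluded = excluded, alpha = alpha,
      notes = c(notes, "zero variance: p = 1 by convention")
    ))
  }
  if (method == "anova_bonferroni") {
    fit <- aov(v2 ~ g2)
    s <- summary(fit)[[1]]
    omnibus <- tibble(method = "anova",
                      statistic = s[["F value"]][1],
                      df = s[["Df"]][1],
                      p_value = s[["Pr(>F)"]][1])
    pt <- stats::pairwise.t.test(v2, g2, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    m <- pt$p.value
    pairs <- which(!is.na(m), arr.ind = TRUE)
    pairwise <- tibble(
      group1 = colnames(m)[pairs[, 2]],
      group2 = rownames(m)[pairs[, 1]],
      p_adj = m[pairs],
      significant = m[pairs] < alpha
    )
  } else {
    kw <- stats::kruskal.test(v2, g2)
    omnibus <- tibble(method = "kruskal_wallis",
                      statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = kw$p.value)
    pairwise <- dunn_posttest(v2, g2, alpha = alpha)
  }
  new_group_comparison(omnibus = omnibus, pairwise = pairwise,
                       excluded = excluded, alpha = alpha, notes = notes)
}

# Dunn's rank-based post-test with tie correction; two-sided z p-values
# multiplied by the number of comparisons (Bonferroni-style family
# adjustment, as in the common GraphPad implementation), capped at 1.
dunn_posttest <- function(v, g, alpha = 0.05) {
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  rbar <- vapply(lv, function(l) mean(r[g == l]), numeric(1))
  ns <- vapply(lv, function(l) sum(g == l), numeric(1))
  pr <- t(utils::combn(lv, 2))
  m <- nrow(pr)
  z <- p <- numeric(m)
  for (i in seq_len(m)) {
    a <- pr[i, 1]; b <- pr[i, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[a] + 1 / ns[b]))
    z[i] <- (rbar[a] - rbar[b]) / se
    p[i] <- min(1, 2 * pnorm(-abs(z[i])) * m)
  }
  tibble(group1 = pr[, 1], group2 = pr[, 2], z = z, p_adj = p,
         significant = p < alpha)
}

new_group_comparison <- function(omnibus, pairwise, excluded, alpha, notes) {
  structure(
    list(omnibus = omnibus, pairwise = pairwise, excluded = excluded,
         alpha = alpha, notes = notes),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise)
  if (nrow(x$excluded)) {
    cat("excluded from testing (n = 1):",
        paste(x$excluded$group, collapse = ", "), "\n")
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
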