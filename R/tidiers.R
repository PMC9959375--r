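#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the edge table of a skeleton graph
#' @param x a `skeleton_graph`.
#' @param ... unused.
#' @return tibble, one row per edge.
#' @export
tidy.skeleton_graph <- function(x, ...) x$edges

#' One-row network summary of a skeleton graph
#' @param x a `skeleton_graph`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.skeleton_graph <- function(x, ...) {
  mt <- mean_tortuosity(x)
  tibble(
    n_branchpoints = sum(x$nodes$kind == "branchpoint"),
    n_endpoints = sum(x$nodes$kind == "endpoint"),
    n_edges = nrow(x$edges),
    n_components = x$n_components,
    total_length_um = sum(x$edges$arc_length_um),
    branchpoint_density_per_um =
      if (sum(x$edges$arc_length_um) > 0) branchpoint_density(x) else NA_real_,
    mean_tortuosity = mt$mean_tortuosity,
    mean_diameter_um = mean(x$edges$mean_diameter_um)
  )
}

#' Tidy pairwise comparisons of a group comparison
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return tibble of pairwise adjusted p-values.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' One-row omnibus summary of a group comparison
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus,
                n_pairs = nrow(x$pairwise),
                n_excluded_groups = nrow(x$excluded),
                alpha = x$alpha)
}
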