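#' Environmental-filtering selections
#'
#' The environmental filtering method selects candidate abiotic-stress
#' populations by threshold rules on their site environment, then caps each
#' subset at `cap` members while keeping the ELC categories of the
#' candidates proportionally represented:
#'
#' * **Drought**: annual De Martonne index below 15 (mid-low semi-arid) and
#'   flowering-season index below 15, ranked from most to least arid during
#'   flowering (`iar_dm_f` ascending, ties by `iar_dm` then `pop_id`).
#' * **Salinity**: topsoil conductivity above 4 dS/m (moderately saline or
#'   higher); if no population qualifies, a fallback tier selects slightly
#'   saline soils (2 < ec < 4 dS/m). The result records which tier fired.
#' * **Waterlogging**: poorly drained topsoil texture (Clay, Silty Clay,
#'   Sandy Clay or Silty Clay Loam) and annual index strictly above 25
#'   (mid-high sub-humid or more humid), ranked from most humid down.
#'
#' Populations flagged `elc_excluded` (no usable ELC category) never enter a
#' selection. Each returned object lists the criteria actually applied, so
#' the thresholds are auditable.
#'
#' @param populations Tibble with the columns the trait rule needs
#'   (`iar_dm`, `iar_dm_f`, `texture_class`, `ec_topsoil`, `elc_category`,
#'   `elc_excluded`, `pop_id`).
#' @param cap Maximum subset size (default 30).
#' @param ec_col Conductivity column for the salinity rule.
#' @return A `pc_subset`: `trait`, `criteria` (tibble of rules applied),
#'   `members` (tibble with `rank` and `rank_key`), `capped`, and for
#'   salinity `tier`.
#' @export
select_drought <- function(populations, cap = 30) {
  populations <- eligible(populations, c("iar_dm", "iar_dm_f"))
  hits <- populations |>
    filter(!is.na(.data$iar_dm), .data$iar_dm < 15) |>
    filter(!is.na(.data$iar_dm_f), .data$iar_dm_f < 15) |>
    arrange(.data$iar_dm_f, .data$iar_dm, .data$pop_id) |>
    mutate(rank_key = .data$iar_dm_f)
  new_subset(
    trait = "drought",
    criteria = tibble(
      variable = c("iar_dm", "iar_dm_f"),
      comparator = c("<", "<"),
      threshold = c(15, 15)
    ),
    hits = hits, cap = cap
  )
}

#' @rdname select_drought
#' @export
select_salinity <- function(populations, cap = 30, ec_col = "ec_topsoil") {
  populations <- eligible(populations, ec_col)
  ec <- populations[[ec_col]]
  tier1 <- populations[!is.na(ec) & ec > 4, ]
  if (nrow(tier1) > 0) {
    hits <- tier1
    tier <- 1L
    criteria <- tibble(variable = ec_col, comparator = ">", threshold = 4)
  } else {
    ec2 <- ec
    hits <- populations[!is.na(ec2) & ec2 > 2 & ec2 < 4, ]
    tier <- 2L
    criteria <- tibble(
      variable = c(ec_col, ec_col), comparator = c(">", "<"), threshold = c(2, 4)
    )
  }
  hits$rank_key <- hits[[ec_col]]
  hits <- arrange(hits, desc(.data$rank_key), .data$pop_id)
  out <- new_subset("salinity", criteria, hits, cap)
  out$tier <- tier
  out$tier1_empty <- tier == 2L
  out
}

#' @rdname select_drought
#' @export
select_waterlogging <- function(populations, cap = 30) {
  populations <- eligible(populations, c("texture_class", "iar_dm"))
  poor_drainage <- c("Clay", "Silty Clay", "Sandy Clay", "Silty Clay Loam")
  hits <- populations |>
    filter(!is.na(.data$texture_class), .data$texture_class %in% poor_drainage) |>
    filter(!is.na(.data$iar_dm), .data$iar_dm > 25) |>
    mutate(rank_key = .data$iar_dm) |>
    arrange(desc(.data$rank_key), .data$pop_id)
  new_subset(
    trait = "waterlogging",
    criteria = tibble(
      variable = c("texture_class", "iar_dm"),
      comparator = c("in", ">"),
      threshold = c(paste(poor_drainage, collapse = "|"), "25")
    ),
    hits = hits, cap = cap
  )
}

eligible <- function(populations, needed) {
  populations <- as_tibble(populations)
  assert_columns(populations, c("pop_id", needed), "populations")
  if (!"elc_category" %in% names(populations)) {
    populations$elc_category <- NA_integer_
  }
  if ("elc_excluded" %in% names(populations)) {
    populations <- filter(populations, !.data$elc_excluded)
  }
  populations
}

new_subset <- function(trait, criteria, hits, cap) {
  descending <- trait %in% c("salinity", "waterlogging")
  capped <- nrow(hits) > cap
  members <- proportional_subset(hits, cap = cap, descending = descending)
  members <- if (descending) {
    arrange(members, desc(.data$rank_key), .data$pop_id)
  } else {
    arrange(members, .data$rank_key, .data$pop_id)
  }
  members <- mutate(members, rank = row_number())
  structure(
    list(
      trait = trait, criteria = criteria,
      members = members, capped = capped,
      n_candidates = nrow(hits)
    ),
    class = "pc_subset"
  )
}

#' @export
print.pc_subset <- function(x, ...) {
  cat(sprintf(
    "<pc_subset> %s: %d member%s of %d candidate%s%s, %d ELC categor%s\n",
    x$trait, nrow(x$members), if (nrow(x$members) == 1) "" else "s",
    x$n_candidates, if (x$n_candidates == 1) "" else "s",
    if (x$capped) " (capped)" else "",
    length(unique(stats::na.omit(x$members$elc_category))),
    if (length(unique(stats::na.omit(x$members$elc_category))) == 1) "y" else "ies"
  ))
  invisible(x)
}

#' Proportional capping of a candidate set across ELC categories
#'
#' If at most `cap` candidates are supplied they are all returned. Otherwise
#' per-category quotas are allocated proportionally to the category counts
#' by largest-remainder (Hamilton) rounding — remainder ties broken in
#' favour of the larger category, then the smaller category id — and each
#' quota is filled with that category's best-ranked candidates by
#' `rank_key`. Largest-remainder rounding minimizes the total absolute
#' deviation from exact proportionality, so a category whose share rounds
#' to zero receives no member.
#'
#' @param candidates Tibble with `elc_category` and `rank_key` (lower is
#'   better unless `descending = TRUE`) columns.
#' @param cap Maximum subset size (default 30).
#' @param descending Fill quotas from the highest `rank_key` down.
#' @return The selected rows of `candidates` (exactly `min(n, cap)` rows).
#' @export
proportional_subset <- function(candidates, cap = 30, descending = FALSE) {
  candidates <- as_tibble(candidates)
  n <- nrow(candidates)
  if (n <= cap) {
    return(candidates)
  }
  assert_columns(candidates, c("elc_category", "rank_key"), "candidates")
  cat_id <- ifelse(is.na(candidates$elc_category), -1L, candidates$elc_category)
  counts <- sort(table(cat_id))
  cats <- as.integer(names(counts))
  n_c <- as.integer(counts)
  quota <- cap * n_c / n
  base <- floor(quota)
  remainder <- quota - base
  leftover <- cap - sum(base)
  if (leftover > 0) {
    ord <- order(-remainder, -n_c, cats)
    base[ord[seq_len(leftover)]] <- base[ord[seq_len(leftover)]] + 1L
  }
  sel <- integer(0)
  for (j in seq_along(cats)) {
    rows <- which(cat_id == cats[j])
    key <- candidates$rank_key[rows]
    ord <- if (descending) {
      order(-key, candidates$pop_id[rows])
    } else {
      order(key, candidates$pop_id[rows])
    }
    sel <- c(sel, rows[ord][seq_len(base[j])])
  }
  candidates[sort(sel), ]
}

#' Overlap report across selected subsets
#'
#' Summarizes which populations appear in more than one trait subset:
#' per-population membership sets, pairwise overlap counts between all
#' subsets, and whether any population is in every subset. Genebank-held
#' status is surfaced when present.
#'
#' @param ... Named `pc_subset` objects and/or tibbles with a `pop_id`
#'   column (e.g. a calibration top subset).
#' @return A `pc_overlap` list: `membership` (tibble: `pop_id`, one logical
#'   column per subset, `n_subsets`, `genebank_held`), `pairwise` (tibble of
#'   subset pairs with overlap counts), `all_four` (ids in every subset).
#' @export
summarize_overlaps <- function(...) {
  inputs <- list(...)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    abort("all subsets must be named", class = "predchar_spec_error")
  }
  member_tbl <- function(x) {
    if (inherits(x, "pc_subset")) x$members else as_tibble(x)
  }
  tabs <- lapply(inputs, member_tbl)
  ids <- unique(unlist(lapply(tabs, function(t) t$pop_id)))
  membership <- tibble(pop_id = ids)
  for (nm in names(tabs)) membership[[nm]] <- ids %in% tabs[[nm]]$pop_id
  membership$n_subsets <- rowSums(as.matrix(membership[names(tabs)]))
  gb <- unlist(lapply(tabs, function(t) {
    if ("genebank_held" %in% names(t)) setNames(t$genebank_held, t$pop_id) else NULL
  }))
  membership$genebank_held <- if (is.null(gb)) NA else unname(gb[match(ids, names(gb))])
  pairs <- utils::combn(names(tabs), 2)
  pairwise <- tibble(
    subset_a = pairs[1, ], subset_b = pairs[2, ],
    overlap = apply(pairs, 2, function(p) {
      sum(membership[[p[1]]] & membership[[p[2]]])
    })
  )
  structure(
    list(
      membership = membership,
      pairwise = pairwise,
      all_subsets = membership$pop_id[membership$n_subsets == length(tabs)]
    ),
    class = "pc_overlap"
  )
}

#' @export
print.pc_overlap <- function(x, ...) {
  cat(sprintf(
    "<pc_overlap> %d populations across %d subsets; %d in more than one, %d in all\n",
    nrow(x$membership), ncol(x$membership) - 3L,
    sum(x$membership$n_subsets > 1), length(x$all_subsets)
  ))
  invisible(x)
}
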