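# Coarse-graining of the full network into functional units, exhaustive
# link-knockout enumeration, screening for the switching phenotype, and
# essential-link extraction.

#' Coarse-grain a network model into functional units
#'
#' Clusters species into functional units via `mapping` and derives the
#' directed, signed inter-unit regulatory links from the reaction list: a
#' link `U -> V` with a given sign exists when some reaction changing a
#' species of unit `V` has a rate factor in a species of unit `U`
#' (sign from the factor's monotonicity times the stoichiometric sign).
#' Parallel couplings with equal sign merge into a single link. When the
#' model carries a link registry, gated parameters are attached to the
#' derived links by name.
#'
#' @param model A `bar_model`.
#' @param mapping Named list `unit -> character vector of species`, covering
#'   every species; defaults to the mapping stored in the model.
#' @return A `bar_coarse` object with `units` and a data frame `links`
#'   (`name`, `from`, `to`, `sign`, `gates`).
#' @export
coarse_grain <- function(model, mapping = model$units) {
  if (is.null(mapping)) stop("no unit mapping supplied")
  sp <- model$species$name
  unit_of <- stats::setNames(rep(names(mapping), lengths(mapping)),
                             unlist(mapping))
  unmapped <- setdiff(sp, names(unit_of))
  if (length(unmapped))
    stop("unmapped species: ", paste(unmapped, collapse = ", "))
  edges <- influence_edges(model)
  # stimulus edge(s)
  stim <- edges$from == ".stimulus"
  edges$from_unit <- ifelse(stim, "S", unit_of[edges$from])
  edges$to_unit <- unit_of[edges$to]
  edges <- edges[edges$from_unit != edges$to_unit, , drop = FALSE]
  key <- paste(edges$from_unit, edges$to_unit, edges$sign)
  uniq <- !duplicated(key)
  links <- data.frame(
    name = paste0(edges$from_unit[uniq],
                  ifelse(edges$sign[uniq] > 0, "->", "-|"),
                  edges$to_unit[uniq]),
    from = edges$from_unit[uniq], to = edges$to_unit[uniq],
    sign = edges$sign[uniq], stringsAsFactors = FALSE)
  # attach registry names and gated parameters, keyed by (from, to, sign)
  reg_key <- vapply(model$links, function(l)
    paste(l$from, l$to, l$sign), "")
  reg <- stats::setNames(model$links, reg_key)
  hit <- reg[paste(links$from, links$to, links$sign)]
  links$name <- ifelse(vapply(hit, is.null, TRUE), links$name,
                       vapply(hit, function(l) l$name %||% "", ""))
  links$gates <- I(lapply(hit, function(l)
    if (is.null(l)) character(0) else unlist(l$gates)))
  structure(list(units = mapping, links = links),
            class = "bar_coarse")
}

#' @export
print.bar_coarse <- function(x, ...) {
  cat("<bar_coarse> ", length(x$units), " functional units, ",
      nrow(x$links), " regulatory links\n", sep = "")
  for (i in seq_len(nrow(x$links)))
    cat("  ", format(x$links$name[i], width = 12), " gates: ",
        paste(x$links$gates[[i]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate all on/off circuit masks
#'
#' @param L Number of links (0 to 20; guarded because the enumeration is
#'   exhaustive).
#' @return Integer matrix with `2^L` rows and `L` columns of 0/1 bits; row
#'   `i` encodes integer `i - 1` (bit 1 = least significant). Row order is
#'   ascending in the integer index.
#' @export
enumerate_masks <- function(L) {
  if (L < 0 || L > 20) stop("link count out of range [0, 20]")
  n <- bitwShiftL(1L, L)
  idx <- 0:(n - 1)
  m <- matrix(0L, n, L)
  for (b in seq_len(L))
    m[, b] <- bitwAnd(bitwShiftR(idx, b - 1L), 1L)
  rownames(m) <- idx
  m
}

#' Knock out regulatory links
#'
#' Returns a copy of the model in which every parameter gated by an
#' off-link is set to zero; on-links are untouched and the input model is
#' unmodified.
#'
#' @param model A `bar_model` with a link registry.
#' @param mask Logical/0-1 vector over the model's registered links (in
#'   registry order), or a character vector of link names to switch off.
#' @return Modified `bar_model`.
#' @export
knockout_links <- function(model, mask) {
  link_names <- vapply(model$links, `[[`, "", "name")
  if (is.character(mask)) {
    bad <- setdiff(mask, link_names)
    if (length(bad)) stop("unknown links: ", paste(bad, collapse = ", "))
    mask <- as.integer(!link_names %in% mask)
  }
  if (length(mask) != length(model$links))
    stop("mask length ", length(mask), " != link count ", length(model$links))
  off <- which(!as.logical(mask))
  gates <- unique(unlist(lapply(model$links[off], function(l) unlist(l$gates))))
  if (length(gates))
    model <- set_model_params(model, stats::setNames(numeric(length(gates)), gates))
  model
}

#' Screen circuit masks of the full model for the switching phenotype
#'
#' For every mask over the selected links, knocks out the off-links,
#' recomputes the basal state and the Bcl-2 dose-response, and classifies
#' switching. Masks whose integration fails are recorded as non-switching
#' with a flag. Work is partitioned deterministically by mask index; a
#' checkpoint file allows long screens to resume.
#'
#' @param model A `bar_model` with a link registry.
#' @param links Character vector of link names to screen (default: all
#'   registered links). Unselected links stay on.
#' @param doses Dose grid used for classification (a coarse grid speeds up
#'   exhaustive screens).
#' @param readout,observation_time Passed to [dose_response()].
#' @param theta_up,theta_down Classifier thresholds.
#' @param checkpoint Optional path of an RDS checkpoint updated every
#'   `checkpoint_every` masks.
#' @param checkpoint_every Integer.
#' @param mask_subset Optional integer vector of mask indices (0-based) to
#'   evaluate, for partitioned/parallel execution; results merge by index.
#' @return Data frame with one row per mask: `index`, `bits`, switching
#'   call summary columns and `failed`.
#' @export
screen_full <- function(model, links = NULL, doses = default_dose_grid(per_decade = 1),
                        readout = "Bcl2", observation_time = 24,
                        theta_up = 1.2, theta_down = 0.8,
                        checkpoint = NULL, checkpoint_every = 256L,
                        mask_subset = NULL) {
  link_names <- vapply(model$links, `[[`, "", "name")
  if (is.null(links)) links <- link_names
  stopifnot(all(links %in% link_names))
  Lp <- length(links)
  masks <- enumerate_masks(Lp)
  idxs <- if (is.null(mask_subset)) 0:(nrow(masks) - 1) else mask_subset
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- readRDS(checkpoint)
    idxs <- setdiff(idxs, done$index)
  }
  rows <- vector("list", length(idxs))
  sel <- match(links, link_names)
  for (ii in seq_along(idxs)) {
    i <- idxs[ii]
    bits <- masks[i + 1, ]
    full_mask <- rep(1L, length(link_names))
    full_mask[sel] <- bits
    mi <- knockout_links(model, full_mask)
    res <- tryCatch({
      crv <- dose_response(mi, doses, readout, observation_time)
      sw <- classify_switching(crv, theta_up = theta_up,
                               theta_down = theta_down)
      data.frame(index = i, bits = paste(bits, collapse = ""),
                 is_switching = sw$is_switching, peak_dose = sw$peak_dose,
                 peak_fold = sw$peak_fold, terminal_fold = sw$terminal_fold,
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(index = i, bits = paste(bits, collapse = ""),
                 is_switching = FALSE, peak_dose = NA_real_,
                 peak_fold = NA_real_, terminal_fold = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    rows[[ii]] <- res
    if (!is.null(checkpoint) && (ii %% checkpoint_every == 0L)) {
      saveRDS(rbind(done, do.call(rbind, rows[seq_len(ii)])), checkpoint)
    }
  }
  out <- rbind(done, do.call(rbind, rows))
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "links") <- links
  if (!is.null(checkpoint)) saveRDS(out, checkpoint)
  out
}

#' Extract essential links from a screen
#'
#' Under the default `"necessity"` criterion a link is essential iff it is
#' on in every switching-capable mask. The alternative
#' `"minimal-sufficient"` criterion returns the smallest on-set whose mask
#' switches while losing switching upon any single link removal (ties broken
#' by mask index).
#'
#' @param screen Result of [screen_full()] (or any data frame with `index`,
#'   `bits`, `is_switching` and a `links` attribute).
#' @param criterion `"necessity"` or `"minimal-sufficient"`.
#' @return Character vector of link names (ordered as screened), with the
#'   criterion attached as an attribute.
#' @export
essential_links <- function(screen, criterion = c("necessity", "minimal-sufficient")) {
  criterion <- match.arg(criterion)
  links <- attr(screen, "links")
  sw <- screen[screen$is_switching & !screen$failed, , drop = FALSE]
  if (!nrow(sw)) stop("no switching-capable masks in the screen")
  bitmat <- do.call(rbind, lapply(strsplit(sw$bits, ""), as.integer))
  if (criterion == "necessity") {
    ess <- links[colSums(bitmat) == nrow(bitmat)]
  } else {
    sizes <- rowSums(bitmat)
    ord <- order(sizes, sw$index)
    ess <- NULL
    all_sw <- stats::setNames(screen$is_switching & !screen$failed,
                              screen$index)
    for (r in ord) {
      bits <- bitmat[r, ]
      on <- which(bits == 1)
      minimal <- all(vapply(on, function(j) {
        drop_idx <- sw$index[r] - bitwShiftL(1L, j - 1L)
        !isTRUE(all_sw[as.character(drop_idx)])
      }, TRUE))
      if (minimal) { ess <- links[on]; break }
    }
    if (is.null(ess)) stop("no minimal sufficient mask found")
  }
  attr(ess, "criterion") <- criterion
  ess
}
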