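#' Default predictor reliability tiers
#'
#' Reliability tiers for the contact predictors commonly combined by
#' consensus-guided folding pipelines, as measured on large training sets:
#' NeBcon, ResPRE and DeepPLM are "very high"; DeepCov, Deepcontact and
#' DNCON2 "high"; MetaPSICOV2 "medium"; GREMLIN, CCMpred and FreeContact
#' "low". Matching is case-insensitive.
#'
#' @return named character vector mapping predictor id to tier.
#' @export
tier_table_default <- function() {
  c(nebcon = "very_high", respre = "very_high", deepplm = "very_high",
    deepcov = "high", deepcontact = "high", dncon2 = "high",
    metapsicov2 = "medium",
    gremlin = "low", ccmpred = "low", freecontact = "low")
}

.tier_levels <- c("very_high", "high", "medium", "low")

#' Tier parameters: per-residue quotas, consensus weights, cutoff bases
#'
#' Quotas (contacts per residue) sum to the 2.4 per-residue selection budget.
#' `base` anchors the confidence cutoff so that selected contacts reach about
#' 50 percent expected precision on calibrated inputs; the cutoff doubles for
#' very shallow alignments (see [min_confidence()]).
#'
#' @return data.frame with one row per tier.
#' @export
tier_params <- function() {
  data.frame(tier = .tier_levels,
             quota = c(1.0, 0.8, 0.4, 0.2),
             weight = c(1.0, 0.8, 0.6, 0.4),
             base = c(0.15, 0.20, 0.25, 0.30),
             stringsAsFactors = FALSE)
}

#' Map predictor identifiers to reliability tiers
#'
#' Unknown predictors fall back to `default` (with a message); known ones use
#' the supplied table.
#'
#' @param predictor_ids character vector.
#' @param tier_table named vector as returned by [tier_table_default()].
#' @param default tier assigned to unknown predictors.
#' @return character vector of tiers, named by predictor.
#' @export
assign_tiers <- function(predictor_ids, tier_table = tier_table_default(),
                         default = "medium") {
  stopifnot(default %in% .tier_levels)
  key <- tolower(predictor_ids)
  tiers <- unname(tier_table[key])
  unknown <- is.na(tiers)
  if (any(unknown)) {
    message("unknown predictor(s) mapped to '", default, "': ",
            paste(predictor_ids[unknown], collapse = ", "))
    tiers[unknown] <- default
  }
  names(tiers) <- predictor_ids
  tiers
}

#' Nf-dependent minimal confidence cutoff
#'
#' `base * (1 + 1 / (1 + nf / 15))`: the cutoff relaxes toward `base` for
#' deep alignments and doubles as the effective depth approaches zero, so
#' shallow-MSA predictions must be roughly twice as confident to be selected.
#'
#' @param tier tier name.
#' @param nf effective alignment depth (> 0).
#' @param params tier parameter table.
#' @return numeric cutoff in `[0, 1]`.
#' @export
min_confidence <- function(tier, nf, params = tier_params()) {
  stopifnot(nf > 0)
  base <- params$base[match(tier, params$tier)]
  if (anyNA(base)) stop("unknown tier: ", paste(tier[is.na(base)], collapse = ","))
  pmin(1, base * (1 + 1 / (1 + nf / 15)))
}

#' Consensus ranking of contacts across predictors
#'
#' Each pair is scored by the sum over maps of `tier_weight * confidence`;
#' ties are broken by larger sequence separation, then lexicographically by
#' `(i, j)`.
#'
#' @param maps list of [contact_map()] sharing the same `L`.
#' @param tiers optional tier per map (defaults to [assign_tiers()] on the
#'   maps' predictor ids).
#' @param params tier parameter table.
#' @return data.frame `(i, j, score, sep)` in descending consensus order.
#' @export
consensus_rank <- function(maps, tiers = NULL, params = tier_params()) {
  stopifnot(length(maps) >= 1L)
  Ls <- vapply(maps, function(m) m$L, 1L)
  if (length(unique(Ls)) != 1L) stop("contact maps disagree on L")
  if (is.null(tiers))
    tiers <- assign_tiers(vapply(maps, function(m) m$predictor_id, ""))
  w <- params$weight[match(tiers, params$tier)]
  rows <- do.call(rbind, lapply(seq_along(maps), function(k) {
    p <- maps[[k]]$predictions
    if (nrow(p) == 0L) return(NULL)
    data.frame(i = p$i, j = p$j, part = w[k] * p$confidence)
  }))
  if (is.null(rows))
    return(data.frame(i = integer(), j = integer(), score = numeric(),
                      sep = integer()))
  agg <- stats::aggregate(part ~ i + j, data = rows, FUN = sum)
  agg$sep <- agg$j - agg$i
  agg <- agg[order(-agg$part, -agg$sep, agg$i, agg$j), , drop = FALSE]
  rownames(agg) <- NULL
  data.frame(i = agg$i, j = agg$j, score = agg$part, sep = agg$sep)
}

#' Select contact restraints from a multi-predictor ensemble
#'
#' Tiers are processed from most to least reliable. Within a tier, all its
#' maps' predictions are pooled (duplicate pairs keep the maximal
#' confidence), filtered by the tier's Nf-dependent cutoff, and taken in
#' descending confidence up to the tier quota (`quota * L` pairs). Pairs
#' already selected by a more reliable tier are skipped; unused quota passes
#' to the next tier down. Well depths are `w_con * confidence` of the
#' selecting record, so the simulation preferentially satisfies confident
#' contacts. The total is capped near the 2.4 per-residue budget.
#'
#' @param maps list of [contact_map()].
#' @param nf effective MSA depth.
#' @param tiers optional tier per map.
#' @param params tier parameter table.
#' @param w_con proportionality constant for well depths.
#' @return data.frame of class `restraint_set` with columns `i`, `j`, `U`,
#'   `confidence`, `predictor`, `tier`, and attributes `L` and `nf`.
#' @export
select_restraints <- function(maps, nf, tiers = NULL, params = tier_params(),
                              w_con = 1.0) {
  stopifnot(length(maps) >= 1L, nf > 0)
  Ls <- vapply(maps, function(m) m$L, 1L)
  if (length(unique(Ls)) != 1L) stop("contact maps disagree on L")
  L <- Ls[1L]
  if (is.null(tiers))
    tiers <- assign_tiers(vapply(maps, function(m) m$predictor_id, ""))
  budget <- ceiling(2.4 * L)
  carry <- 0
  chosen <- list()
  seen <- character(0)
  for (t in .tier_levels) {
    idx <- which(tiers == t)
    quota <- floor(params$quota[params$tier == t] * L) + carry
    if (length(idx) == 0L) { carry <- quota; next }
    pool <- do.call(rbind, lapply(idx, function(k) {
      p <- maps[[k]]$predictions
      if (nrow(p) == 0L) return(NULL)
      data.frame(i = p$i, j = p$j, confidence = p$confidence,
                 predictor = maps[[k]]$predictor_id, stringsAsFactors = FALSE)
    }))
    if (is.null(pool)) { carry <- quota; next }
    pool <- pool[order(-pool$confidence, pool$i, pool$j), , drop = FALSE]
    pool <- pool[!duplicated(pool[c("i", "j")]), , drop = FALSE]
    cutoff <- min_confidence(t, nf, params)
    pool <- pool[pool$confidence >= cutoff, , drop = FALSE]
    key <- paste(pool$i, pool$j)
    pool <- pool[!(key %in% seen), , drop = FALSE]
    take <- min(nrow(pool), quota, budget - length(seen))
    if (take > 0L) {
      sel <- pool[seq_len(take), , drop = FALSE]
      sel$tier <- t
      chosen[[t]] <- sel
      seen <- c(seen, paste(sel$i, sel$j))
    }
    carry <- quota - max(take, 0L)
  }
  out <- if (length(chosen) > 0L) do.call(rbind, chosen) else
    data.frame(i = integer(), j = integer(), confidence = numeric(),
               predictor = character(), tier = character())
  out$U <- w_con * out$confidence
  out <- out[order(out$i, out$j),
             c("i", "j", "U", "confidence", "predictor", "tier")]
  rownames(out) <- NULL
  attr(out, "L") <- L
  attr(out, "nf") <- nf
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d restraints, L = %d (budget 2.4L = %.0f)\n",
              nrow(x), attr(x, "L"), 2.4 * attr(x, "L")))
  NextMethod()
}

#' Convert a restraint set to a contact map
#'
#' @param rs a `restraint_set`.
#' @param predictor_id label for the resulting map.
#' @return A [contact_map()] carrying the selecting confidences.
#' @export
restraints_as_map <- function(rs, predictor_id = "selected") {
  contact_map(attr(rs, "L"),
              data.frame(i = rs$i, j = rs$j, confidence = rs$confidence),
              predictor_id)
}
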