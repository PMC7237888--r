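# Seeded generators for every input the pipeline consumes, with recorded
# ground truth, so all stages are testable without downloads. Strings only
# need set semantics: no VDJ recombination model is attempted.

# Derive a per-component substream seed from the top-level seed, so adding a
# generator never perturbs existing outputs. Kept below 2^31.
substream_seed <- function(seed, component) {
  offsets <- c(repertoire_human = 1L, repertoire_mouse = 2L, public_pool = 3L,
               autoreactive = 4L, clones = 5L)
  stopifnot(component %in% names(offsets))
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[component]]
}

random_cdr3 <- function(n, min_len = 8, max_len = 20, cass_prefix = TRUE) {
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  vapply(lens, function(L) {
    if (cass_prefix && L > 4) {
      paste0("CASS", paste(sample(.AA_ALPHABET, L - 4, replace = TRUE),
                           collapse = ""))
    } else {
      paste(sample(.AA_ALPHABET, L, replace = TRUE), collapse = "")
    }
  }, character(1))
}

# n unique CDR3-like strings not colliding with `exclude`.
unique_cdr3 <- function(n, exclude = character(), ...) {
  out <- character(0)
  guard <- 0
  while (length(out) < n) {
    cand <- random_cdr3(2 * (n - length(out)) + 8, ...)
    cand <- setdiff(unique(cand), c(exclude, out))
    out <- c(out, cand)
    guard <- guard + 1
    if (guard > 100) stop("could not generate enough unique sequences",
                          call. = FALSE)
  }
  out[seq_len(n)]
}

#' Specification for synthetic TCR repertoires with planted ground truth
#'
#' @param n_subjects Named vector/list with `human` and `mouse` subject counts.
#' @param sequences_per_subject Background (private) sequences per subject.
#' @param public_pool_size Number `S` of public sequences planted per species.
#' @param public_min_share Fraction of subjects each public sequence is
#'   planted into (at least `ceiling(public_min_share * n_subjects)`).
#' @param n_cross_species Number `c <= S` of public sequences shared verbatim
#'   between the two species' pools.
#' @param n_autoreactive Total autoreactive sequences generated.
#' @param n_planted_matches Number `k <= S` of autoreactive sequences copied
#'   verbatim from the public pools (these are the recoverable matches).
#' @param seed Top-level integer seed; fans out to per-component substreams.
#' @return A list of class `synth_repertoire_spec`.
#' @export
synth_repertoire_spec <- function(n_subjects = c(human = 12, mouse = 8),
                                  sequences_per_subject = 30,
                                  public_pool_size = 20,
                                  public_min_share = 0.9,
                                  n_cross_species = 5,
                                  n_autoreactive = 40,
                                  n_planted_matches = 6,
                                  seed = 1L) {
  n_subjects <- unlist(n_subjects)
  stopifnot(all(c("human", "mouse") %in% names(n_subjects)),
            all(n_subjects >= 1),
            sequences_per_subject >= 0,
            public_pool_size >= 0, n_cross_species >= 0,
            n_autoreactive >= 0, n_planted_matches >= 0,
            public_min_share > 0, public_min_share <= 1)
  if (n_cross_species > public_pool_size) {
    stop("n_cross_species must be <= public_pool_size", call. = FALSE)
  }
  if (n_planted_matches > public_pool_size) {
    stop("n_planted_matches must be <= public_pool_size", call. = FALSE)
  }
  if (n_planted_matches > n_autoreactive) {
    stop("n_planted_matches must be <= n_autoreactive", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects,
                 sequences_per_subject = sequences_per_subject,
                 public_pool_size = public_pool_size,
                 public_min_share = public_min_share,
                 n_cross_species = n_cross_species,
                 n_autoreactive = n_autoreactive,
                 n_planted_matches = n_planted_matches,
                 seed = as.integer(seed)),
            class = "synth_repertoire_spec")
}

plant_public <- function(pool, subjects, min_share) {
  min_carriers <- ceiling(min_share * length(subjects))
  choices <- seq(min_carriers, length(subjects))
  rows <- lapply(pool, function(s) {
    # length-safe draw: sample(n, 1) on a scalar would expand to 1:n
    n_carriers <- choices[sample.int(length(choices), 1)]
    tibble::tibble(subject_id = sample(subjects, n_carriers), cdr3_aa = s)
  })
  dplyr::bind_rows(rows)
}

#' Generate synthetic repertoires, an autoreactive set, and ground truth
#'
#' Emulates per-subject CDR3beta repertoires with a shared (public) pool per
#' species, a cross-species core, and autoreactive sequences planted verbatim
#' from the public pools. Background sequences are unique across subjects and
#' pools (collision-checked), so recovered counts equal planted counts
#' exactly. Fully reproducible from the spec's seed.
#'
#' @param spec A [synth_repertoire_spec()].
#' @return A list: `human` and `mouse` (`repertoire_table`s), `autoreactive`
#'   (`autoreactive_set`), `min_subjects` (named, the thresholds that recover
#'   the planted pools), and `ground_truth` (`S` per species, `c`, `k`, plus
#'   the planted sequence vectors).
#' @examples
#' syn <- gen_repertoires(synth_repertoire_spec(seed = 42))
#' pub <- build_public_set(syn$human, syn$min_subjects[["human"]])
#' length(pub$sequences) == syn$ground_truth$S
#' @export
gen_repertoires <- function(spec) {
  stopifnot(inherits(spec, "synth_repertoire_spec"))
  S <- spec$public_pool_size

  # public pools: c shared sequences + species-private remainders
  pools <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, "public_pool"))
    shared <- unique_cdr3(spec$n_cross_species)
    hu_only <- unique_cdr3(S - spec$n_cross_species, exclude = shared)
    mo_only <- unique_cdr3(S - spec$n_cross_species,
                           exclude = c(shared, hu_only))
    list(human = c(shared, hu_only), mouse = c(shared, mo_only),
         shared = shared)
  })

  gen_species <- function(sp_name) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, paste0("repertoire_", sp_name)))
    ns <- spec$n_subjects[[sp_name]]
    subjects <- sprintf("%s_%03d", sp_name, seq_len(ns))
    pool <- pools[[sp_name]]
    background <- unique_cdr3(ns * spec$sequences_per_subject,
                              exclude = c(pools$human, pools$mouse))
    bg <- tibble::tibble(
      subject_id = rep(subjects, each = spec$sequences_per_subject),
      cdr3_aa = background)
    pub <- if (S > 0) plant_public(pool, subjects, spec$public_min_share)
           else tibble::tibble(subject_id = character(), cdr3_aa = character())
    df <- dplyr::bind_rows(bg, pub)
    df$species <- sp_name
    as_repertoire(df)
  }
  human <- gen_species("human")
  mouse <- gen_species("mouse")

  auto <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, "autoreactive"))
    k <- spec$n_planted_matches
    planted <- if (k > 0) sample(unique(c(pools$human, pools$mouse)), k)
               else character(0)
    novel <- unique_cdr3(spec$n_autoreactive - k,
                         exclude = c(pools$human, pools$mouse,
                                     human$cdr3_aa, mouse$cdr3_aa))
    seqs <- c(planted, novel)
    as_autoreactive(tibble::tibble(
      cdr3_aa = seqs,
      disease = sample(c("T1D", "thyroiditis", "vitiligo"), length(seqs),
                       replace = TRUE),
      antigen = sample(c("proinsulin", "thyroglobulin", "PMEL"), length(seqs),
                       replace = TRUE),
      species = "human"))
  })
  planted_all <- intersect(auto$cdr3_aa, c(pools$human, pools$mouse))

  min_subjects <- vapply(c(human = "human", mouse = "mouse"), function(sp) {
    ceiling(spec$public_min_share * spec$n_subjects[[sp]])
  }, numeric(1))

  list(human = human, mouse = mouse, autoreactive = auto,
       min_subjects = min_subjects,
       ground_truth = list(S = S, c = spec$n_cross_species,
                           k = spec$n_planted_matches,
                           public_human = pools$human,
                           public_mouse = pools$mouse,
                           core = pools$shared,
                           planted_matches = planted_all))
}

# Save/restore .Random.seed so generators behave as pure functions of their
# spec without clobbering the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write synthetic repertoires to TSV (plus ground-truth JSON sidecar)
#'
#' Writes `human.tsv`, `mouse.tsv`, `autoreactive.tsv` and
#' `ground_truth.json` into `dir`, in the formats the analysis stages read.
#'
#' @param syn Result of [gen_repertoires()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_repertoires <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(human = file.path(dir, "human.tsv"),
             mouse = file.path(dir, "mouse.tsv"),
             autoreactive = file.path(dir, "autoreactive.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  readr::write_tsv(syn$human, paths[["human"]])
  readr::write_tsv(syn$mouse, paths[["mouse"]])
  readr::write_tsv(syn$autoreactive, paths[["autoreactive"]])
  jsonlite::write_json(syn$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Specification for synthetic clone populations
#'
#' @param n_clones Number of clones.
#' @param u Either a numeric vector of point-mass distortions (recycled to
#'   `n_clones`) or `NULL` to draw log-normal distortions.
#' @param sigma Log-normal sigma for drawn distortions (meanlog 0).
#' @param x0 Initial abundances, recycled to `n_clones`.
#' @param seed Integer seed.
#' @return A list of class `synth_clone_spec`.
#' @export
synth_clone_spec <- function(n_clones = 3, u = NULL, sigma = 0.2, x0 = 1,
                             seed = 1L) {
  stopifnot(n_clones >= 1, sigma >= 0)
  structure(list(n_clones = n_clones, u = u, sigma = sigma, x0 = x0,
                 seed = as.integer(seed)),
            class = "synth_clone_spec")
}

#' Generate a clone population, or a named scenario preset
#'
#' The `"competition"` preset is the standard three-clone contest: wild type
#' at `x0 = 1` against a hypersecreting mutant (`u = 2`) and a hyposecreting
#' mutant (`u = 0.5`), each starting at half the wild-type abundance. Run it
#' with `n = 5` and `gamma` 0.01 / 0.25 / 2 for the takeover, surveillance and
#' autoimmune outcomes respectively. The `"pair"` preset drops the
#' hyposecretor (wild type vs `u = 2`), the configuration used for phase-plane
#' analysis.
#'
#' @param spec A [synth_clone_spec()], or ignored when `preset` is given.
#' @param preset `NULL`, `"competition"`, or `"pair"`.
#' @return A [clones()] table.
#' @examples
#' gen_clone_population(preset = "competition")
#' @export
gen_clone_population <- function(spec = synth_clone_spec(), preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("competition", "pair"))
    return(switch(preset,
      competition = clones(u = c(1, 2, 0.5), x = c(1, 0.5, 0.5)),
      pair = clones(u = c(1, 2), x = c(1, 0.5))))
  }
  stopifnot(inherits(spec, "synth_clone_spec"))
  u <- if (!is.null(spec$u)) {
    rep_len(spec$u, spec$n_clones)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, "clones"))
    stats::rlnorm(spec$n_clones, meanlog = 0, sdlog = spec$sigma)
  }
  clones(u = u, x = rep_len(spec$x0, spec$n_clones))
}
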