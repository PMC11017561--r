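# Self-contained synthetic benchmark generator: drug structures drawn from a
# packaged vocabulary of real small molecules, Gaussian expression and
# Bernoulli mutation profiles, and synergy labels from a planted linear +
# interaction function of the MACCS bits and the expression profile. The
# defaults (20 drugs, 10 cell lines, 500 records, label noise sd 5, scores
# rescaled to sd 20) define the package's reference study conditions.

#' Packaged drug vocabulary
#'
#' Sixty-three curated, pre-validated SMILES of diverse drug-like small
#' molecules (every entry parses, has at least four heavy atoms and a
#' non-empty torsion fingerprint). Used by [generate_drugs()].
#'
#' @return Named character vector of SMILES.
#' @export
drug_vocabulary <- function() {
  c(aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    naproxen = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
    nicotine = "CN1CCCC1c1cccnc1",
    salicylic_acid = "Oc1ccccc1C(=O)O",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    phenobarbital = "CCC1(c2ccccc2)C(=O)NC(=O)NC1=O",
    metformin = "CN(C)C(=N)NC(=N)N",
    valproic_acid = "CCCC(CCC)C(=O)O",
    gabapentin = "NCC1(CC(=O)O)CCCCC1",
    theophylline = "CN1C(=O)N(C)c2[nH]cnc2C1=O",
    isoniazid = "NNC(=O)c1ccncc1",
    pyrazinamide = "NC(=O)c1cnccn1",
    nicotinamide = "NC(=O)c1cccnc1",
    phenylephrine = "CNCC(O)c1cccc(O)c1",
    ephedrine = "CNC(C)C(O)c1ccccc1",
    amphetamine = "CC(N)Cc1ccccc1",
    dopamine = "NCCc1ccc(O)c(O)c1",
    serotonin = "NCCc1c[nH]c2ccc(O)cc12",
    histamine = "NCCc1c[nH]cn1",
    melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    tyrosine = "NC(Cc1ccc(O)cc1)C(=O)O",
    phenylalanine = "NC(Cc1ccccc1)C(=O)O",
    leucine = "CC(C)CC(N)C(=O)O",
    glutamine = "NC(CCC(N)=O)C(=O)O",
    citric_acid = "OC(=O)CC(O)(C(=O)O)CC(=O)O",
    glucose = "OCC1OC(O)C(O)C(O)C1O",
    ascorbic_acid = "OCC(O)C1OC(=O)C(O)=C1O",
    ketoprofen = "CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1",
    diclofenac = "OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    imipramine = "CN(C)CCCN1c2ccccc2CCc2ccccc21",
    diphenhydramine = "CN(C)CCOC(c1ccccc1)c1ccccc1",
    chloroquine = "CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12",
    sulfanilamide = "Nc1ccc(S(N)(=O)=O)cc1",
    sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
    trimethoprim = "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    coumarin = "O=C1C=Cc2ccccc2O1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
    salbutamol = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    adenine = "Nc1ncnc2[nH]cnc12",
    uracil = "O=C1C=CNC(=O)N1",
    thymine = "CC1=CNC(=O)NC1=O",
    furosemide = "NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl",
    hydrochlorothiazide = "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",
    indomethacin = "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1",
    mefenamic_acid = "Cc1cccc(Nc2ccccc2C(=O)O)c1C",
    antipyrine = "CC1=CC(=O)N(c2ccccc2)N1C",
    carbamazepine = "NC(=O)N1c2ccccc2C=Cc2ccccc21",
    phenytoin = "O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1",
    quinoline = "c1ccc2ncccc2c1",
    sulfadiazine = "Nc1ccc(S(=O)(=O)Nc2ncccn2)cc1",
    benzamide = "NC(=O)c1ccccc1",
    cimetidine = "CC1=C(CSCCNC(=NC)NC#N)N=CN1",
    ranitidine = "CNC(=CN(=O)=O)NCCSCc1ccc(CN(C)C)o1")
}

#' Synthetic study configuration
#'
#' @param n_drugs,n_cells,n_records Numbers of drugs, cell lines, and
#'   (drug pair, cell line) records; `n_records` may not exceed
#'   `n_cells * choose(n_drugs, 2)`.
#' @param g_expr,g_mut Gene counts of the expression and mutation panels.
#' @param sigma_label Gaussian label noise sd (on the raw planted-score
#'   scale, before rescaling).
#' @param effect_weights Length-3 vector `(w_drug, w_cell, w_interaction)`
#'   weighting the additive drug term, the cell-line term and the drug-drug
#'   interaction term of the planted score.
#' @param mutation_rate Bernoulli rate of the mutation profiles.
#' @param score_scale Final labels are standardized to mean 0 and this sd,
#'   mimicking the magnitude of screening synergy scores.
#' @param seed Master seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 20L, n_cells = 10L, n_records = 500L,
                             g_expr = 128L, g_mut = 128L, sigma_label = 5,
                             effect_weights = c(w_drug = 1, w_cell = 1,
                                                w_interaction = 1),
                             mutation_rate = 0.1, score_scale = 20,
                             seed = 1L) {
  max_rec <- n_cells * choose(n_drugs, 2)
  if (n_records > max_rec) {
    stop_domain(sprintf("n_records (%d) exceeds the %d possible trios",
                        n_records, max_rec))
  }
  if (sigma_label < 0) stop_domain("sigma_label must be >= 0")
  structure(list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
                 n_records = as.integer(n_records), g_expr = as.integer(g_expr),
                 g_mut = as.integer(g_mut), sigma_label = sigma_label,
                 effect_weights = effect_weights,
                 mutation_rate = mutation_rate, score_scale = score_scale,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Sample drugs from the packaged vocabulary
#'
#' @param n Number of drugs (at most `length(drug_vocabulary())`).
#' @param seed Integer seed.
#' @return Data frame with columns `id` (the compound name) and `smiles`.
#' @export
generate_drugs <- function(n, seed = 1L) {
  vocab <- drug_vocabulary()
  if (n > length(vocab)) stop_vocabulary_exhausted(n, length(vocab))
  pick <- .with_seed(seed, sample(names(vocab), n))
  data.frame(id = pick, smiles = unname(vocab[pick]), stringsAsFactors = FALSE)
}

#' Generate a synthetic cell-line panel
#'
#' Expression values are i.i.d. standard normal per (cell, gene); mutations
#' are i.i.d. Bernoulli. Gene symbols are synthetic (`G0001...` for
#' expression, `M0001...` for mutation) and cell ids are `CL01...`.
#'
#' @param n_cells,g_expr,g_mut Panel dimensions.
#' @param mutation_rate Bernoulli rate; default 0.1.
#' @param seed Integer seed.
#' @return List with `expression`, `mutation` (matrices with cell ids as row
#'   names) and `panel` (list of ordered gene symbol vectors
#'   `expression_genes`, `mutation_genes`).
#' @export
generate_cell_panel <- function(n_cells, g_expr, g_mut, mutation_rate = 0.1,
                                seed = 1L) {
  cells <- sprintf("CL%02d", seq_len(n_cells))
  eg <- sprintf("G%04d", seq_len(g_expr))
  mg <- sprintf("M%04d", seq_len(g_mut))
  .with_seed(seed, {
    expr <- matrix(stats::rnorm(n_cells * g_expr), n_cells, g_expr,
                   dimnames = list(cells, eg))
    mut <- matrix(stats::rbinom(n_cells * g_mut, 1L, mutation_rate),
                  n_cells, g_mut, dimnames = list(cells, mg))
    list(expression = expr, mutation = mut,
         panel = list(expression_genes = eg, mutation_genes = mg))
  })
}

#' Planted synergy labels for a set of trios
#'
#' The raw score of trio (i, j, c) is
#' `w_drug <u, f_i + f_j> + w_cell <v, e_c> + w_int <r, f_i * f_j> + eps`,
#' where `f` are MACCS fingerprint vectors, `e_c` the expression profile,
#' `u`, `v`, `r` fixed standard-normal weight vectors drawn once from the
#' configuration seed, and `eps ~ N(0, sigma_label^2)`. The scores are then
#' standardized to mean 0 and sd `score_scale`. The construction is
#' symmetric under drug-order swap.
#'
#' @param trios Data frame with `drug_a`, `drug_b`, `cell_line`.
#' @param maccs Drugs-by-166 MACCS matrix with drug ids as row names.
#' @param expression Cells-by-genes expression matrix.
#' @param cfg A [synthetic_config()].
#' @return Numeric score vector, one per trio.
#' @export
generate_labels <- function(trios, maccs, expression, cfg) {
  .check_records(trios)
  w <- cfg$effect_weights
  ia <- match(as.character(trios$drug_a), rownames(maccs))
  ib <- match(as.character(trios$drug_b), rownames(maccs))
  ic <- match(as.character(trios$cell_line), rownames(expression))
  if (anyNA(ia) || anyNA(ib)) stop_data_coverage("trio references unknown drug")
  if (anyNA(ic)) stop_data_coverage("trio references unknown cell line")
  .with_seed(cfg$seed, {
    u <- stats::rnorm(ncol(maccs))
    v <- stats::rnorm(ncol(expression))
    r <- stats::rnorm(ncol(maccs))
    fa <- maccs[ia, , drop = FALSE]
    fb <- maccs[ib, , drop = FALSE]
    raw <- w[[1]] * drop((fa + fb) %*% u) +
      w[[2]] * drop(expression[ic, , drop = FALSE] %*% v) +
      w[[3]] * drop((fa * fb) %*% r)
    if (cfg$sigma_label > 0) {
      raw <- raw + stats::rnorm(length(raw), sd = cfg$sigma_label)
    }
    mu <- mean(raw)
    sdv <- stats::sd(raw)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    unname((raw - mu) / sdv * cfg$score_scale)
  })
}

#' Random dose-response fixtures
#'
#' Draws `n` random parameter sets (`m > 0`, shape in `[0.5, 4]`,
#' `r_min < r_max`) together with random 3x3 to 5x5 observed/expected grids
#' with growth fractions in `[0, 1.2]`.
#'
#' @param n Number of fixtures.
#' @param seed Integer seed.
#' @return List of `n` elements, each with `params`
#'   ([dose_response_params()]) and `grid` ([combination_grid()]).
#' @export
generate_dose_grids <- function(n, seed = 1L) {
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r_min <- stats::runif(1, 0, 30)
      params <- dose_response_params(
        r_min = r_min,
        r_max = r_min + stats::runif(1, 10, 90),
        m = stats::runif(1, 0.1, 10),
        lam = stats::runif(1, 0.5, 4))
      p <- sample(3:5, 1L)
      q <- sample(3:5, 1L)
      grid <- combination_grid(
        observed = matrix(stats::runif(p * q, 0, 1.2), p, q),
        expected = matrix(stats::runif(p * q, 0, 1.2), p, q))
      list(params = params, grid = grid)
    })
  })
}

#' Generate a complete synthetic synergy study
#'
#' Samples drugs and a cell panel, draws `n_records` distinct (unordered
#' drug pair, cell line) trios, featurizes the drugs and plants synergy
#' labels. The result bundles everything the training and evaluation
#' functions consume.
#'
#' @param cfg A [synthetic_config()].
#' @param n_bits,dims HashTT / MAP4 fingerprint lengths.
#' @return List with `records` (drug_a, drug_b, cell_line, score), `drugs`
#'   (id, smiles), `features` (fingerprint matrices + expression +
#'   mutation), `panel` and `config`.
#' @export
generate_synergy_dataset <- function(cfg = synthetic_config(),
                                     n_bits = 512L, dims = 512L) {
  drugs <- generate_drugs(cfg$n_drugs, seed = cfg$seed)
  panel <- generate_cell_panel(cfg$n_cells, cfg$g_expr, cfg$g_mut,
                               mutation_rate = cfg$mutation_rate,
                               seed = cfg$seed + 1L)
  pairs <- utils::combn(sort(drugs$id), 2L)
  grid <- expand.grid(pair = seq_len(ncol(pairs)),
                      cell = rownames(panel$expression),
                      stringsAsFactors = FALSE)
  pick <- .with_seed(cfg$seed + 2L,
                     sample.int(nrow(grid), cfg$n_records))
  trios <- data.frame(drug_a = pairs[1L, grid$pair[pick]],
                      drug_b = pairs[2L, grid$pair[pick]],
                      cell_line = grid$cell[pick],
                      stringsAsFactors = FALSE)
  featurized <- featurize_drug_table(drugs, n_bits = n_bits, dims = dims)
  fp <- fingerprint_matrices(featurized)
  trios$score <- generate_labels(trios, fp$maccs, panel$expression, cfg)
  list(records = trios, drugs = drugs,
       features = list(fingerprints = fp,
                       expression = panel$expression,
                       mutation = panel$mutation),
       panel = panel$panel, config = cfg)
}
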