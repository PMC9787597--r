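#' Pipeline composition configuration
#'
#' A composition is an ordered subset of the five stages
#' \itemize{
#'   \item \code{DA} random-transformation augmentation (jitter + shift),
#'   \item \code{ZP} zero-padding of the training data,
#'   \item \code{GAN} the 1-D Wasserstein GAN (always required),
#'   \item \code{DAE} denoising of generated spectra,
#'   \item \code{RZP} removal of the padded channels from generated spectra.
#' }
#' Stages before GAN preprocess the training data; stages after GAN
#' post-process generated spectra in listed order, so
#' \code{"DA-ZP-GAN-DAE-RZP"} denoises at padded length and then cuts the
#' padding, while \code{"DA-ZP-GAN-RZP-DAE"} cuts first and denoises at the
#' original length.  The DAE is trained at whichever length it will see.
#'
#' @param composition character vector of stages in order, or a single
#'   hyphen-separated string such as \code{"DA-ZP-GAN-DAE-RZP"}.
#' @param length unpadded spectrum length L.
#' @param pad_len padding P per end used by ZP/RZP; \code{length + 2*pad_len}
#'   must be divisible by 16 when ZP is used (\code{length} itself otherwise).
#' @param aug an \code{\link{augmentationConfig}} for the DA stage.
#' @param gan_epochs,dae_epochs training epochs of the two models.
#' @param base_channels GAN width passed to \code{\link{ganConfig}}.
#' @param noise_size,corruption_sigma forwarded to the model configs.
#' @param rng_seed master seed for the whole pipeline.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(composition = c("DA", "ZP", "GAN", "DAE", "RZP"),
                           length = 2688L, pad_len = 64L,
                           aug = augmentationConfig(),
                           gan_epochs = 100L, dae_epochs = 100L,
                           base_channels = 64L, noise_size = 100L,
                           corruption_sigma = NULL, rng_seed = 1L) {
  if (length(composition) == 1L && grepl("-", composition))
    composition <- strsplit(composition, "-", fixed = TRUE)[[1L]]
  known <- c("DA", "ZP", "GAN", "DAE", "RZP")
  if (!all(composition %in% known))
    stop("unknown stage(s): ",
         paste(setdiff(composition, known), collapse = ", "))
  if (anyDuplicated(composition)) stop("stages must be unique")
  gpos <- match("GAN", composition)
  if (is.na(gpos)) stop("the composition must contain GAN")
  if ("ZP" %in% composition && match("ZP", composition) > gpos)
    stop("ZP must precede GAN")
  if ("DA" %in% composition && match("DA", composition) > gpos)
    stop("DA must precede GAN")
  if ("RZP" %in% composition) {
    if (!"ZP" %in% composition) stop("RZP requires ZP")
    if (match("RZP", composition) < gpos) stop("RZP must follow GAN")
  }
  if ("DAE" %in% composition && match("DAE", composition) < gpos)
    stop("DAE must follow GAN")
  if (is.null(corruption_sigma)) corruption_sigma <- aug$sigma_max
  structure(list(composition = composition, length = as.integer(length),
                 pad_len = as.integer(pad_len), aug = aug,
                 gan_epochs = as.integer(gan_epochs),
                 dae_epochs = as.integer(dae_epochs),
                 base_channels = as.integer(base_channels),
                 noise_size = as.integer(noise_size),
                 corruption_sigma = corruption_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "PipelineConfig")
}

# length of the spectra the DAE sees during generation (and so during its
# own training): padded unless RZP runs before DAE
.dae_length <- function(cfg) {
  comp <- cfg$composition
  padded <- "ZP" %in% comp
  if (padded && "RZP" %in% comp && "DAE" %in% comp &&
      match("RZP", comp) < match("DAE", comp))
    cfg$length
  else if (padded) cfg$length + 2L * cfg$pad_len
  else cfg$length
}

#' Train the models of a pipeline composition
#'
#' First training process: the seed spectra are augmented (DA) and/or
#' zero-padded (ZP) per the composition, and the Wasserstein GAN is trained
#' on the result.  Second training process: when the composition includes
#' DAE, the autoencoder is trained on clean seed spectra (cycled to the
#' augmentation count, padded to the length the DAE will operate at) with
#' synthetic Gaussian corruption.
#'
#' @param seed_set a \linkS4class{SpectrumSet} of seed spectra of length
#'   \code{cfg$length}.
#' @param cfg a \code{\link{pipelineConfig}}.  The master \code{cfg$rng_seed}
#'   governs every stage: the DA stage is re-seeded from it (any seed on the
#'   aug config is ignored here), and the GAN and DAE derive their seeds from
#'   it, so the whole training run reproduces from the one master seed.
#' @return list of class \code{"pipelineModels"}: \code{gan}, \code{dae}
#'   (NULL when absent), \code{cfg}.
#' @export
runTraining <- function(seed_set, cfg) {
  stopifnot(is(seed_set, "SpectrumSet"), inherits(cfg, "PipelineConfig"))
  if (nChannels(seed_set) != cfg$length)
    stop("seed spectra have length ", nChannels(seed_set),
         " but cfg$length is ", cfg$length)
  comp <- cfg$composition
  train <- seed_set
  if ("DA" %in% comp) {
    aug <- cfg$aug
    aug$rng_seed <- cfg$rng_seed
    train <- augmentSet(seed_set, aug)
  }
  datasize <- cfg$length
  if ("ZP" %in% comp) {
    train <- addZeroPadding(train, cfg$pad_len)
    datasize <- cfg$length + 2L * cfg$pad_len
  }
  gcfg <- ganConfig(datasize, noise_size = cfg$noise_size,
                    base_channels = cfg$base_channels,
                    epochs = cfg$gan_epochs, rng_seed = cfg$rng_seed)
  gan <- trainGAN(train, gcfg)
  dae <- NULL
  if ("DAE" %in% comp) {
    dlen <- .dae_length(cfg)
    n_clean <- if ("DA" %in% comp) cfg$aug$n_out else
      max(nSpectra(seed_set), 20L)
    clean <- intensities(seed_set)[, rep_len(seq_len(nSpectra(seed_set)),
                                             n_clean), drop = FALSE]
    if (dlen > cfg$length)
      clean <- addZeroPadding(clean, (dlen - cfg$length) %/% 2L)
    dcfg <- daeConfig(dlen, corruption_sigma = cfg$corruption_sigma,
                      epochs = cfg$dae_epochs, rng_seed = cfg$rng_seed + 1L)
    dae <- trainDAE(clean, dcfg)
  }
  structure(list(gan = gan, dae = dae, cfg = cfg), class = "pipelineModels")
}

#' Generate spectra with trained pipeline models
#'
#' Generation process: noise codes go through the generator; the stages
#' listed after GAN in the composition are then applied in order (denoising
#' and/or removal of the padded channels).
#'
#' @param models a \code{"pipelineModels"} list from \code{\link{runTraining}}.
#' @param n number of spectra to generate.
#' @param rng_seed seed for the noise draws (defaults to the pipeline seed).
#' @return a \linkS4class{SpectrumSet}; spectrum length is \code{cfg$length}
#'   when the composition removes its padding, otherwise the padded length.
#' @export
runGeneration <- function(models, n, rng_seed = NULL) {
  stopifnot(inherits(models, "pipelineModels"))
  cfg <- models$cfg
  if (is.null(rng_seed)) rng_seed <- cfg$rng_seed
  out <- sampleGenerator(models$gan, n, rng_seed = rng_seed)
  comp <- cfg$composition
  post <- comp[seq_along(comp) > match("GAN", comp)]
  for (stage in post) {
    out <- switch(stage,
      DAE = denoise(models$dae, out),
      RZP = removePadding(out, cfg$pad_len))
  }
  out
}

#' Ablation study over pipeline compositions
#'
#' Trains and evaluates one pipeline per composition with matched seeds, so
#' differences between rows reflect the composition, not sampling.  Each row
#' scores \code{n_generate} generated spectra against \code{real_set} with
#' the Frechet distance, Pearson correlation and Euclidean distance.
#'
#' @param seed_set seed spectra (length \code{cfg$length}).
#' @param real_set held-out reference spectra of length \code{cfg$length}
#'   standing in for real-world data.
#' @param variants list of compositions (each a character vector or
#'   hyphen-joined string).  Defaults to the five canonical rows from
#'   GAN-only up to the full system.
#' @param cfg a \code{\link{pipelineConfig}} template; its composition field
#'   is replaced by each variant in turn.
#' @param n_generate generated spectra per variant.
#' @return data.frame with columns \code{composition}, \code{fid},
#'   \code{pcc}, \code{ed}; one row per variant.
#' @export
runAblation <- function(seed_set, real_set,
                        variants = list("GAN", "DA-GAN", "DA-GAN-DAE",
                                        "DA-ZP-GAN-RZP-DAE",
                                        "DA-ZP-GAN-DAE-RZP"),
                        cfg, n_generate = 50L) {
  rows <- lapply(variants, function(v) {
    vcfg <- pipelineConfig(composition = v, length = cfg$length,
                           pad_len = cfg$pad_len, aug = cfg$aug,
                           gan_epochs = cfg$gan_epochs,
                           dae_epochs = cfg$dae_epochs,
                           base_channels = cfg$base_channels,
                           noise_size = cfg$noise_size,
                           corruption_sigma = cfg$corruption_sigma,
                           rng_seed = cfg$rng_seed)
    models <- runTraining(seed_set, vcfg)
    gen <- runGeneration(models, n_generate, rng_seed = cfg$rng_seed + 99L)
    if (nChannels(gen) != nChannels(real_set))
      stop("variant ", paste(vcfg$composition, collapse = "-"),
           " generates length ", nChannels(gen),
           "; evaluation needs length ", nChannels(real_set),
           " (add RZP or drop ZP)")
    rep <- evaluateGeneration(real_set, gen,
                              composition_label =
                                paste(vcfg$composition, collapse = "-"))
    data.frame(composition = rep$composition_label, fid = rep$fid,
               pcc = rep$pcc, ed = rep$ed)
  })
  do.call(rbind, rows)
}
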