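# Shared configuration for the analysis drivers.
#
# The cohort emulates the study design: 10 subjects, six perturbation
# conditions (Stick0.4/0.2, Slip0.2/0.4, M1, L1), perturbations at right
# mid-stance with one random catch stride per five-stride batch. Block
# lengths are scaled down from the 2/4/2-minute protocol to 40/60/20
# strides so the whole cohort reruns in well under a minute; every phase
# definition still applies unchanged.
#
# Response models are synthetic: the deltas below set the *direction* and
# centimetre scale of the emulated reactions (step-length/width changes,
# XCOM shifts, anticipatory adjustments on catch strides) and an
# exponential adaptation constant of ~10 strides. They are inputs to the
# simulation, not estimates from human data. Because the walker is a
# kinematic template, the passive body-inertia surge that a belt
# perturbation imparts to the real COM is not emergent; it is emulated
# through the xcom_* deltas (a stick throws the body forward relative to
# the slowed belt, hence a large positive xcom_ap_lhs; a slip the
# converse), on top of the template's own belt/platform surface coupling.

library(stridestab)

N_SUBJECTS <- 10
COHORT_SEED <- 20210901L
SUBJECT_SD <- 0.15          # between-subject scaling SD of response deltas
NOISE_SD <- 0.001           # 1 mm marker noise

BLOCKS <- c(pre = 40 * 1.1 / 60, perturb = 60 * 1.1 / 60,
            post = 20 * 1.1 / 60)

GAIT <- gait_config(noise_sd = NOISE_SD)

scale_resp <- function(resp, f)
  response_model(delta = resp$delta * f, catch_delta = resp$catch_delta * f,
                 tau = resp$tau)

RESPONSES <- list(
  "Stick0.4" = response_model(
    delta = c(bos_ap_lhs = -0.040, xcom_ap_lhs = 0.160, bos_ml_lhs = 0.020,
              bos_ml_lto = 0.015, xcom_ap_lto = 0.010),
    catch_delta = c(bos_ml_lto = 0.010, xcom_ap_lto = 0.008),
    tau = 12),
  "Slip0.4" = response_model(
    delta = c(bos_ap_lhs = 0.060, xcom_ap_lhs = -0.022, bos_ml_lhs = 0.015,
              bos_ap_lto = 0.020, xcom_ap_lto = 0.015),
    catch_delta = c(bos_ap_lto = 0.012, xcom_ap_lto = 0.010),
    tau = 12),
  "M1" = response_model(
    delta = c(bos_ml_lhs = 0.005, xcom_ml_lhs = 0.020),
    catch_delta = c(bos_ml_lto = 0.008),
    tau = 10),
  "L1" = response_model(
    delta = c(bos_ml_lhs = 0.045, xcom_ml_lhs = 0.014, bos_ml_lto = 0.012),
    catch_delta = c(bos_ml_lto = 0.008),
    tau = 10)
)
RESPONSES[["Stick0.2"]] <- scale_resp(RESPONSES[["Stick0.4"]], 0.5)
RESPONSES[["Slip0.2"]] <- scale_resp(RESPONSES[["Slip0.4"]], 0.5)

CONDITIONS <- names(RESPONSES)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
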