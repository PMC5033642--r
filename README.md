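# tdcsdcm

Effective-connectivity analysis of concurrent tDCS–fMRI picture naming,
packaged as a tested, fully reproducible pipeline.

## The problem

Anodal transcranial direct current stimulation (tDCS) over left frontal
cortex during overt picture naming speeds naming responses and reduces the
BOLD signal in the left inferior frontal sulcus (IFS) and left ventral
premotor cortex (VPM). The question this package addresses is mechanistic:
**how does stimulation change the directed coupling between and within
these two regions, and does the size of each person's coupling change
predict the size of their behavioural facilitation?**

The tool of choice is a deterministic two-region Dynamic Causal Model
(DCM). Neuronal activity follows the bilinear state equation

    dx/dt = (A + B_c) x + C u(t)

with intrinsic coupling `A` (Hz), condition-specific modulation `B_c`
(anodal vs sham), driving-input gains `C`, and stick inputs `u` at picture
onsets; the neuronal states are observed through the balloon–Windkessel
haemodynamic model and the standard BOLD observation equation. Negative
self-connections encode each region's activity decay; `halfLife(a) =
log(0.5)/a` converts one to seconds. Models are fitted by variational
Laplace (Gauss–Newton with Levenberg damping on the free-energy bound
`F = accuracy − KL(posterior ‖ prior)`), compared by fixed-effects
Bayesian model selection over a crossed six-model space, and summarized by
sampling-based Bayesian model averaging; condition differences are judged
by a two-distribution test at 95% exceedance, and brain–behaviour
association by a two-tailed Pearson correlation between per-subject
connectivity change and percentage naming facilitation.

Who it is for: researchers who want a transparent, scriptable, fully
testable implementation of this analysis style — including a synthetic
cohort generator that reproduces the study design (107 trials per session
in blocks of 6 with 7 s rests, ITI 3.92 s, TR 3.36 s, 344 volumes, two
sessions, 10 subjects) so every stage can be validated without imaging
data.

## Worked example

Simulate a small cohort under the study conditions, fit two candidate
architectures to every subject, select and average models, test the
condition contrasts, and analyse behaviour:

```r
library(tdcsdcm)

halfLife(c(-0.26, -0.09))      # 2.665951 7.701635  (seconds)
currentDensity(2, 5, 7)        # 0.05714286         (mA/cm^2)

cs     <- cohortSpec(nSubjects = 4, seed = 1)   # defaults = study conditions
design <- designSpec()                          # 344 volumes, 107 trials
cohort <- simulateCohort(cs, design, dt = 0.2)

space <- buildModelSpace()[c("bidirectional-inVPM", "forward-inIFS")]
fits  <- invertCohort(cohort, space, design,
                      settings = list(maxIter = 12, dt = 0.2))
bms   <- ffxBms(evidenceTable(fits))
round(bms$group, 3)
#> bidirectional-inVPM       forward-inIFS
#>                   1                   0

bma <- bmaSample(bms$bySubject, fits, nSamples = 10000, seed = 2)
contrastTable(bma, seed = 3)
#>   connection mean_anodal  mean_sham pct_anodal pct_sham significant direction
#> 1   IFS self  -0.4590586 -0.4246063     44.935   55.065       FALSE       a<b
#> 2   IFS->VPM  -0.5495731 -0.3289760     27.135   72.865       FALSE       a<b
#> 3   VPM->IFS   0.7494137  0.6376614     62.650   37.350       FALSE       a>b
#> 4   VPM self  -0.2190598 -0.2589053     53.935   46.065       FALSE       a>b

cl <- cleanTrials(cohort$trials); cl$log
#>   nInput nAccuracy nVoiceKey nOutlier nRetained pctExcluded
#> 1    856        25        15       45       771    9.929907
m  <- conditionMeans(cl$trials, "subject")
round(rtChangePercent(m$anodal, m$sham), 2)
#> [1]  17.44  20.37  17.89 -12.77
```

Reading the output: the input-to-VPM architecture wins model selection
decisively; the backward IFS→VPM connection is more negative under anodal
stimulation (−0.55 vs −0.33 Hz, exceedance 73% — in the planted direction
but below the 95% criterion at 4 subjects) and the VPM self-connection
less negative (−0.22 vs −0.26 Hz); per-subject facilitation varies widely,
as the generator plants a 10%-SD spread around a 3.35% mean. `runPipeline()`
chains all stages (including the brain–behaviour correlation table) and
writes JSON artifacts with provenance blocks; `inst/scripts/tdcsdcm` is a
thin command-line wrapper with `simulate | invert | bms | bma | behaviour
| report` subcommands.

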