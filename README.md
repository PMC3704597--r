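# gaitSubspace

Decomposition of dichotomous kinematic gait data into a **classifying
subspace** and its non-classifying **orthogonal complement**.

## The problem

Two experimental conditions — say, running in shoes with a viscoelastic
versus an elastic midsole — change a movement only subtly: the difference is
buried under the far larger amplitude of the movement itself and under
intra- and inter-subject variability. Principal component analysis (PCA)
orders base vectors by *variance*, so condition differences hide in
scattered higher-order components. This package instead builds a basis
ordered by **classifiability**: directions in which held-out subjects'
trials can be assigned to the correct condition better than chance.

It is aimed at movement scientists working with marker-based motion capture
of a dichotomous design (two conditions, several subjects, repeated
trials).

## The method

Each trial's 13 markers × 3 axes × 101 normalized stance time points are
concatenated into one row vector, giving a trials × 3939 matrix *M* (440 ×
3939 for 11 subjects × 2 conditions × 20 trials). Every variable is
whitened within subject,

    M'[j,k] = (M[j,k] − mean_s(k)) / sd_s(k),

with mean and SD taken over all of subject *s*'s trials and conditions, so
*M'* has zero mean and unit SD for every variable in every subject block.

The **SVM space** is extracted iteratively. At step *m*, a linear-kernel
SVM is fitted leaving one subject out; its discriminant is the data-space
vector *d* = Σᵢ αᵢ yᵢ xᵢ over the support vectors, and the held-out
subject's trials are classified with the fold's decision function
f(x) = ⟨x, d⟩ + b. A subject is *classifiable* when enough trials are
assigned correctly under a one-sided binomial test (p = 0.5, α = 0.05); the
*classification rate* is the fraction of classifiable subjects, itself
gated by a subject-level binomial test. If the rate is significant, the
mean of the sign-aligned fold discriminants becomes SVM base vector *eₘ*,
the data are deflated to the orthogonal complement (x → x − ⟨x,eₘ⟩eₘ), and
the iteration repeats; otherwise it stops. The final complement is
summarized by PCA, so SVM basis + complement PCA basis form a full
orthonormal basis with an explained-variance fraction per vector.

Within the SVM space, an extended-infomax **ICA** yields a non-orthogonal
basis of statistically independent directions; exactly one of them — the
*ICA discriminant* — is expected to separate the conditions. Candidate
discriminants (best classifying PCA vector, first SVM vector, ICA
discriminant) are ranked by Cohen's d of their condition projections (gated
by a Lilliefors normality check).

The movement component living in any subspace is reconstructed in metric
coordinates via

    x_rec = Σ_k ⟨x', e_k⟩ e_k   →   diag(sd_s) x_rec + mean_s,

and can be exported as condition-superimposed stick-figure frames with the
between-condition difference magnified (factor 5 by default).

Because no motion-capture recordings are distributed, the package includes
a synthetic-data generator that emulates the study design (11 × 2 × 20
trials, 13 markers, 101 points) with subject random effects, trial noise,
and a planted low-dimensional condition effect whose direction is known —
every stage of the pipeline is validated against this ground truth.

## Worked example

```r
library(gaitSubspace)

sim <- generateSynthetic(syntheticConfig(seed = 7))   # planted effect, SNR 10
rep <- runPipeline(sim$trials, rule = classifiabilityRule("paper"),
                   icaSeed = 7, maxPcaVectors = 10)

rep$objects$decomposition
#> DecompositionResult: SVM space dim 1, complement dim 428 (rate-drop)
#>   SVM-space variance fraction: 0.0108
#>   mean classification rate: 100.0%

rep$objects$ica
#> IcaResult (infomax, seed 7): 1 vector(s)
#>   discriminant: vector 1 (rate 100.0%, |d| = 225.11)

truthAlignment(rep$objects$decomposition, sim$truth)$scores
#> [1] 0.8878085
```

Reading the numbers: the planted condition effect is recovered as a single
SVM base vector that classifies 11/11 held-out subjects (rate 100%) while
explaining only 1.1% of the total movement variance — the signature of a
small but perfectly classifiable condition difference. The ICA of the 1-D
SVM space returns that same direction as the ICA discriminant. The
alignment score is the |cosine| between the planted whitened-space
direction and its projection onto the recovered SVM space. Effect sizes on
this clean synthetic data are far larger than anything seen on real
recordings, because the generator's noise is homogeneous and the planted
effect is exactly low-dimensional.

The classifying movement component can then be visualized:

```r
ke  <- rep$objects$experiment
rec <- reconstructMovement(ke, svmBasis(rep$objects$decomposition))
exportFrames(conditionAverage(rec), plane = "sagittal", magnification = 5,
             file = "frames_sagittal.csv")
```

A thin command-line wrapper over the same pipeline is provided in
`inst/scripts/run_pipeline.R`.

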