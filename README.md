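# emgstress

Detecting driver stress from a single surface-EMG channel with
statistical time features, rank-based feature selection and kernel SVM
classification.

## The problem

Stress while driving raises the tonic activity of postural muscles such
as the right trapezius, and a single low-rate (15.5 Hz) surface EMG
amplitude channel recorded during a rest / city / highway driving
protocol carries enough information to classify a 5-minute window as
stressed (`SC`) or not stressed (`NSC`). The difficulty is twofold: raw
EMG amplitude differs across subjects by large factors (electrode
placement, skin impedance), and the within-subject effect of stress is a
subtle change in amplitude *variability*, not in the visible waveform.

`emgstress` is aimed at physiological-computing practitioners who want a
fully deterministic, testable implementation of this pipeline:

1. cut one 5-min window from the initial rest interval and from each of
   two city and two highway intervals (5 windows per subject; 50 for a
   10-subject cohort);
2. z-score all of a subject's windows with the rest window's mean μ and
   population standard deviation σ: x̃ = (x − μ)/σ;
3. compute 17 statistical time features per window — grouped mode, mean,
   range, variance, standard deviation, impulse factor, square mean root
   (SMR), shape factors over SMR and RMS, RMS, crest factor, latitude
   factor, and RMS-normalized central moments 3–6, plus the median
   (850 feature values for 50 windows);
4. rank features by the tie-corrected Kruskal–Wallis statistic
   H between the NSC and SC groups (χ² upper-tail p-value) and keep the
   top features below α = 0.01 (variance and standard deviation, with
   median and SMR excluded by an explicit overlap veto);
5. cross-validate six SVM kernels (linear; quadratic and cubic
   (1 + u·v)^d; Gaussian exp(−‖u−v‖²/s²) at fine/medium/coarse
   bandwidths √P/4, √P, 4√P) and a 2-10-2 tanh MLP trained by
   Levenberg–Marquardt, under stratified seeded 10-fold CV, reporting
   accuracy, sensitivity, specificity and rank-method AUC across window
   lengths of 1–5 minutes.

A seedable synthetic cohort generator reproduces the statistical
structure the method relies on (log-normal inter-subject amplitude
nuisance, scenario variance multipliers 2×/3× for city/highway,
Poisson-timed transient bursts), so the whole pipeline runs and is
tested with no external data.

## Worked example

```r
library(emgstress)

cfg <- study_config(n_subjects = 10, seed = 42)
report <- run_study(cfg)
print(report)
```

```
Driver-stress study report
  selected features: variance, std 
  best kernel: linear 
  accuracy matrix (%):
                1min 2min 3min 4min 5min
linear            98   96   98  100  100
quadratic         96   96   98   98   98
cubic            100  100  100  100  100
fine_gaussian    100  100  100  100  100
medium_gaussian   98   96   98  100  100
coarse_gaussian   80   80   80   82  100
  classifier comparison:
   classifier accuracy auc sensitivity specificity
 SVM (linear)      100   1         100         100
          MLP      100   1         100         100
```

```r
head(report$pvalues, 4)
```

```
   feature        H      p_value
1 variance 23.71733 1.115734e-06
2      std 23.71733 1.115734e-06
3      rms 23.71733 1.115734e-06
4    range 23.52941 1.230188e-06
```

Reading the output: the Kruskal–Wallis ranking puts variance and
standard deviation at the 10-vs-40 perfect-separation floor
p = 1.116e-06 — after rest-baseline normalization every stress window's
variance ratio exceeds the rest value of exactly 1 — and those two
features are selected as classifier inputs. The accuracy matrix shows
the window-length effect: short windows are noisier (burst-count
variability inflates 1-min variance estimates) and accuracy rises with
window length, saturating at 5 min. On this synthetic cohort separation
is near-perfect at 5 min for most kernels (the real-data analogue of
this study reports 96% there), and the SVM matches or beats the MLP
comparator. `best_kernel` is the first kernel attaining the maximal
5-min accuracy.

Individual stages are available as plain functions
(`generate_cohort()`, `extract_segments()`, `normalize_segments()`,
`extract_stf()`, `kruskal_wallis()`, `rank_features()`,
`select_features()`, `train_svm()`, `train_mlp()`, `crossvalidate()`,
`compare_classifiers()`), and `run_study(cfg, out_dir = "...")` writes
`pvalues.csv`, `accuracy_matrix.csv`, `comparison.csv`, per-length
feature tables and `report.json`.

See `vignettes/driver-stress-emg.Rmd` for the model, the feature
conventions, the generator's design and its limitations.

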