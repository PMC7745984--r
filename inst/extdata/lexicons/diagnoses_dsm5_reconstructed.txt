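# Psychiatric diagnosis lexicon, DSM-5-derived.
# RECONSTRUCTED DEFAULT: a best-effort list assembled from commonly audited
# DSM-5 categories and their vocabulary phrase forms. It is editable and is
# meant to be replaced by the analyst's own curated list; every audit records
# this file's MD5 hash so results are tied to the exact list used.
adhd adhd ADHD
alcoholism alcoholism Alcoholism alcholism
anxiety anxiety Anxiety
anxiety_disorders anxiety_disorders Anxiety_Disorders anxiety_disorder
bipolar_disorder bipolar_disorder Bipolar_disorder bi_polar_disorder
depression depression Depression
major_depressive_disorder major_depressive_disorder Major_Depressive_Disorder
perinatal_depression perinatal_depression Perinatal_depression
postpartum_depression postpartum_depression post_partum_depression Postpartum_depression
seasonal_affective_disorder seasonal_affective_disorder Seasonal_Affective_Disorder
schizophrenia schizophrenia Schizophrenia
schizoaffective_disorder schizoaffective_disorder Schizoaffective_disorder
obsessive_compulsive obsessive_compulsive Obsessive_compulsive obsessive_compulsive_disorder OCD
compulsive_hoarding compulsive_hoarding Compulsive_hoarding
compulsive_gambling compulsive_gambling Compulsive_gambling
substance_abuse substance_abuse Substance_abuse
substance_use substance_use Substance_use
addiction addiction Addiction
ptsd ptsd PTSD
paranoia paranoia Paranoia
psychosis psychosis Psychosis
panic_disorder panic_disorder Panic_disorder
social_anxiety social_anxiety Social_anxiety
anorexia anorexia Anorexia anorexia_nervosa
bulimia bulimia Bulimia bulimia_nervosa
autism autism Autism
insomnia insomnia Insomnia
dementia dementia Dementia
hypochondria hypochondria Hypochondria
mental_illness mental_illness Mental_illness
borderline_personality_disorder borderline_personality_disorder Borderline_personality_disorder
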