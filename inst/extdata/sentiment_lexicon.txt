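# Miniature valence lexicon (VADER file format: token<TAB>valence).
# Sentiment-bearing words used by the synthetic-corpus templates plus
# negatively valenced health keywords (neutralized before scoring).
love	3.0
great	2.8
good	1.9
awesome	3.1
amazing	2.8
best	3.2
better	1.9
smooth	1.5
favorite	2.0
happy	2.7
enjoy	2.2
nice	1.8
perfect	2.7
relief	1.9
safe	1.4
awful	-2.9
bad	-2.5
terrible	-3.0
hate	-2.7
worse	-2.1
worst	-3.1
horrible	-2.5
nasty	-2.6
harsh	-1.6
sick	-2.1
scared	-1.9
worried	-1.4
die	-2.9
kills	-3.2
burn	-1.5
cough	-1.2
wheezing	-1.1
asthma	-1.3
phlegm	-0.9
pain	-2.3
headache	-1.7
dizziness	-1.3
migraine	-1.9
seizure	-2.2
anxiety	-1.9
depression	-2.6
insomnia	-1.6
nausea	-1.9
vomiting	-2.2
diarrhea	-1.9
ache	-1.8
sore	-1.4
irritation	-1.5
scratchy	-1.1
cancer	-3.4
tumor	-2.6
carcinoma	-2.4
fatigue	-1.5
rash	-1.4
itching	-1.3
swelling	-1.2
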