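# RPED occurrence by clinical-benefit status, one row per subject with a
# known RPED/benefit combination: 13 subjects with clinical benefit (3 with
# RPED), 32 without clinical benefit (5 with RPED), and 3 RPED subjects with
# unassessable benefit (excluded from the association test). Subject
# identifiers are synthetic placeholders; the marginal counts are the data.
subject	benefit	rped
B01	benefit	TRUE
B02	benefit	TRUE
B03	benefit	TRUE
B04	benefit	FALSE
B05	benefit	FALSE
B06	benefit	FALSE
B07	benefit	FALSE
B08	benefit	FALSE
B09	benefit	FALSE
B10	benefit	FALSE
B11	benefit	FALSE
B12	benefit	FALSE
B13	benefit	FALSE
N01	no_benefit	TRUE
N02	no_benefit	TRUE
N03	no_benefit	TRUE
N04	no_benefit	TRUE
N05	no_benefit	TRUE
N06	no_benefit	FALSE
N07	no_benefit	FALSE
N08	no_benefit	FALSE
N09	no_benefit	FALSE
N10	no_benefit	FALSE
N11	no_benefit	FALSE
N12	no_benefit	FALSE
N13	no_benefit	FALSE
N14	no_benefit	FALSE
N15	no_benefit	FALSE
N16	no_benefit	FALSE
N17	no_benefit	FALSE
N18	no_benefit	FALSE
N19	no_benefit	FALSE
N20	no_benefit	FALSE
N21	no_benefit	FALSE
N22	no_benefit	FALSE
N23	no_benefit	FALSE
N24	no_benefit	FALSE
N25	no_benefit	FALSE
N26	no_benefit	FALSE
N27	no_benefit	FALSE
N28	no_benefit	FALSE
N29	no_benefit	FALSE
N30	no_benefit	FALSE
N31	no_benefit	FALSE
N32	no_benefit	FALSE
U01	unassessable	TRUE
U02	unassessable	TRUE
U03	unassessable	TRUE
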