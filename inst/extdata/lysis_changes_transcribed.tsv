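# Transcription of knockout-vs-wild-type lysis changes stated in prose for
# three resistance-gene knockouts (predicted change: increased lysis) on a
# subset of the O157 typing-phage panel. Grades are synthetic stand-ins chosen
# to realise the stated directions only; they are NOT measured plate values:
#  - wild type fully lytic to TP3 and TP13, fully resistant to TP16
#  - fcl and waaL: increased lysis generally (TP5 as representative) and
#    conversion of TP16 from resistant to susceptible
#  - sspA: increased lysis generally but no conversion for TP16
#  - waaL and sspA: effect on TP14 opposite the prediction (decreased)
#  - fcl: effect on TP3 opposite the prediction (decreased)
strain	TP3	TP5	TP13	TP14	TP16
WT	+	(+)	+	(+)	-
fcl	(+)	+	+	(+)	+
waaL	+	+	+	-	+
sspA	+	+	+	-	-
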