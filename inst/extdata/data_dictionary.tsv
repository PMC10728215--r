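table	column	type	units	description
eda.tsv	participant	character	-	participant identifier (e.g. p01)
eda.tsv	video	character	-	video identifier (e.g. awe-1)
eda.tsv	condition	character	-	emotion condition: neutral, amusement or awe
eda.tsv	time_s	numeric	seconds	time since video onset (250 Hz grid)
eda.tsv	value	numeric	microsiemens	skin conductance
pupil.tsv	participant	character	-	participant identifier
pupil.tsv	video	character	-	video identifier
pupil.tsv	condition	character	-	emotion condition
pupil.tsv	time_s	numeric	seconds	time since video onset (120 Hz grid)
pupil.tsv	value	numeric	millimetres	pupil diameter; NA during blink dropouts
joystick.tsv	participant	character	-	participant identifier
joystick.tsv	video	character	-	video identifier
joystick.tsv	condition	character	-	emotion condition
joystick.tsv	time_s	numeric	seconds	time since video onset
joystick.tsv	value	numeric	0-0.5	joystick inclination (0 upright, 0.5 fully right)
trials.tsv	participant	character	-	participant identifier
trials.tsv	video	character	-	video identifier
trials.tsv	condition	character	-	emotion condition
trials.tsv	order_within	integer	1 or 2	presentation order within the condition
trials.tsv	awe	numeric	1-7	post-video awe rating (composite)
trials.tsv	amusement	numeric	1-7	post-video amusement rating
trials.tsv	small_self	numeric	1-7	perceived self-size rating
trials.tsv	self_boundary	numeric	1-7	perceived self-boundary rating
trials.tsv	agency	numeric	1-7	supernatural agency rating
trials.tsv	non_agency	numeric	1-7	supernatural non-agency rating
trials.tsv	fear	numeric	1-7	fear rating (control-model covariate)
trials.tsv	temperature	numeric	degrees C	laboratory temperature (participant-constant)
trials.tsv	humidity	numeric	percent	laboratory humidity (participant-constant)
trials.tsv	age	numeric	years	participant age
trials.tsv	gender	character	f/m	participant gender code
ground_truth_events.tsv	participant	character	-	participant identifier
ground_truth_events.tsv	video	character	-	video identifier
ground_truth_events.tsv	condition	character	-	emotion condition
ground_truth_events.tsv	onset	numeric	seconds	true injected SCR event onset
ground_truth_events.tsv	amplitude	numeric	microsiemens	true injected SCR amplitude
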