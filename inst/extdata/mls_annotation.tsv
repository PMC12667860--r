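name	first	last	role
mls	650	776	element
window_520_770	520	770	sufficient
window_525_775	525	775	sufficient
window_400_650	400	650	insufficient
window_405_655	405	655	insufficient
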