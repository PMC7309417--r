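family	member
miR-3/309/318	miR-3
miR-3/309/318	miR-309
miR-3/309/318	miR-318
miR-9a/9b/9c	miR-9a
miR-9a/9b/9c	miR-9b
miR-9a/9b/9c	miR-9c
miR-92a/92b/310/312/313	miR-92a
miR-92a/92b/310/312/313	miR-92b
miR-92a/92b/310/312/313	miR-310
miR-92a/92b/310/312/313	miR-312
miR-92a/92b/310/312/313	miR-313
miR-276a/276b	miR-276a
miR-276a/276b	miR-276b
miR-279/286/996	miR-279
miR-279/286/996	miR-286
miR-279/286/996	miR-996
miR-285/995/998	miR-285
miR-285/995/998	miR-995
miR-285/995/998	miR-998
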