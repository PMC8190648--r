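a
an
and
are
at
be
by
for
from
in
into
of
on
or
per
s
the
to
via
was
were
with
without
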